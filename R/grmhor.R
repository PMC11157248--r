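#' Full higher-order repeat analysis of a monomer set or genomic sequence
#'
#' The package's central entry point. Starting from either detected
#' monomers or raw sequence plus a consensus query, it (i) clusters
#' monomers into families at the divergence `threshold`, (ii) computes MD
#' points, the GRM histogram and classified MD-line segments, (iii) splits
#' the monomers into tandem array segments, and (iv) for every array with a
#' detected HOR period infers the canonical unit, partitions the array into
#' canonical/variant copies and lays each copy out as a cascading aligned
#' scheme.
#'
#' @param x input: an `hor_monomers` data frame (from [scan_monomers()] or
#'   [read_monomers_fasta()]), a FASTA path / character / `DNAStringSet`
#'   subject (scanned first; supply `query`), or an `hor_array_sim` /
#'   `hor_chromosome_sim` (scanned with its own ancestor query).
#' @param query consensus query for scanning; ignored when `x` is already a
#'   monomer set.
#' @param max_div scanner divergence cutoff, see [scan_monomers()].
#' @param threshold family divergence threshold (default 0.05).
#' @param max_period,min_support,max_gap periodicity parameters, see
#'   [compute_md_points()] and [detect_segments()].
#' @param max_gap_bp array segmentation gap, see [segment_arrays()].
#' @param families_method clustering mode, see [assign_families()].
#' @return object of class `grm_hor`: list with `monomers`, `families`,
#'   `md_points`, `grm`, `segments`, `arrays`, `schemes` (one entry per
#'   array with a HOR period: `unit`, `copies`, `summary`, `first_index`),
#'   and `params`.
#' @examples
#' spec <- hor_array_spec(unit = c(1:15, 1, 16), n_copies = 8, seed = 42)
#' sim <- build_array(spec)
#' fit <- grm_hor(sim)
#' fit
#' summary(fit)
#' @export
grm_hor <- function(x, query = NULL, max_div = 0.30, threshold = 0.05,
                    max_period = 50, min_support = 10, max_gap = NULL,
                    max_gap_bp = 2000,
                    families_method = c("auto", "exact", "stream")) {
  families_method <- match.arg(families_method)
  if (inherits(x, "hor_array_sim") || inherits(x, "hor_chromosome_sim")) {
    if (is.null(query)) query <- x$query
    x <- x$sequence
  }
  monomers <- if (inherits(x, "hor_monomers")) x else
    scan_monomers(x, query = query, max_div = max_div)

  if (nrow(monomers) < 2) {
    warning("fewer than 2 monomers; diagrams are empty")
    empty_pts <- data.frame(index = integer(0), period = integer(0))
    return(structure(list(
      monomers = monomers,
      families = if (nrow(monomers)) hor_families(monomers, threshold) else NULL,
      md_points = empty_pts, grm = grm_histogram(empty_pts),
      segments = classify_segments(detect_segments(empty_pts, min_support)),
      arrays = segment_arrays(monomers, integer(nrow(monomers)), max_gap_bp),
      schemes = list(),
      params = list(max_div = max_div, threshold = threshold,
                    max_period = max_period, min_support = min_support,
                    max_gap = max_gap, max_gap_bp = max_gap_bp)),
      class = "grm_hor"))
  }

  families <- hor_families(monomers, threshold = threshold,
                           method = families_method)
  labels <- families$labels
  md <- compute_md_points(labels, max_period = max_period)
  grm <- grm_histogram(md)
  segments <- classify_segments(detect_segments(md, min_support = min_support,
                                                max_gap = max_gap))
  arrays <- segment_arrays(monomers, labels, max_gap_bp = max_gap_bp,
                           max_period = max_period, min_support = min_support,
                           max_gap = max_gap)
  schemes <- list()
  for (a in seq_len(nrow(arrays))) {
    n <- arrays$hor_period[a]
    if (is.na(n)) next
    sel <- monomers$index >= arrays$first_index[a] &
      monomers$index <= arrays$last_index[a]
    labs <- labels[sel]
    if (length(labs) < 2L * n) next
    unit <- infer_canonical_unit(labs, n)
    copies <- partition_copies(labs, unit)
    schemes[[length(schemes) + 1L]] <- list(
      array_id = arrays$array_id[a],
      first_index = arrays$first_index[a],
      start_bp = monomers$start[sel],
      unit = unit, copies = copies,
      summary = summarize_array(copies))
  }
  structure(list(monomers = monomers, families = families, md_points = md,
                 grm = grm, segments = segments, arrays = arrays,
                 schemes = schemes,
                 params = list(max_div = max_div, threshold = threshold,
                               max_period = max_period,
                               min_support = min_support, max_gap = max_gap,
                               max_gap_bp = max_gap_bp)),
            class = "grm_hor")
}

#' @export
print.grm_hor <- function(x, ...) {
  cat("<grm_hor> higher-order repeat analysis\n")
  cat(sprintf("  monomers: %d\n", nrow(x$monomers)))
  cat(sprintf("  families: %d\n", if (is.null(x$families)) 0L else x$families$k))
  cat(sprintf("  MD points: %d  (top periods: %s)\n", nrow(x$md_points),
              if (nrow(x$grm)) {
                g <- x$grm[order(-x$grm$count), ][seq_len(min(4, nrow(x$grm))), ]
                paste(sprintf("%d@%d", g$count, g$period), collapse = ", ")
              } else "none"))
  cat(sprintf("  MD-line segments: %d (%d HOR)\n", nrow(x$segments),
              sum(x$segments$kind == "HOR")))
  cat(sprintf("  arrays: %d; aligned schemes: %d\n", nrow(x$arrays),
              length(x$schemes)))
  for (sc in x$schemes) {
    cat(sprintf("    array %d: %dmer (tau = %d, %s), %d copies, %d%% canonical\n",
                sc$array_id, sc$unit$n, sc$unit$tau,
                if (sc$unit$tau < sc$unit$n) "cascading" else "Willard's type",
                sc$summary$n_copies, sc$summary$pct_canonical))
  }
  invisible(x)
}

#' @method summary grm_hor
#' @export
summary.grm_hor <- function(object, ...) {
  arr <- object$arrays
  arr$hor_period <- as.integer(arr$hor_period)
  arr$subfragments <- vapply(arr$subfragment_periods,
                             function(v) paste(v, collapse = ","), character(1))
  arr$subfragment_periods <- NULL
  arr$tau <- NA_integer_
  arr$n_copies <- NA_integer_
  arr$pct_canonical <- NA_integer_
  for (sc in object$schemes) {
    i <- match(sc$array_id, arr$array_id)
    arr$tau[i] <- sc$unit$tau
    arr$n_copies[i] <- sc$summary$n_copies
    arr$pct_canonical[i] <- sc$summary$pct_canonical
  }
  structure(list(arrays = arr, k = if (is.null(object$families)) 0L else
    object$families$k, n_monomers = nrow(object$monomers)),
    class = "summary.grm_hor")
}

#' @export
print.summary.grm_hor <- function(x, ...) {
  cat(sprintf("HOR analysis summary: %d monomers, %d families, %d arrays\n",
              x$n_monomers, x$k, nrow(x$arrays)))
  print(x$arrays, row.names = FALSE)
  invisible(x)
}

#' Plot GRM and MD diagrams
#'
#' `which = "grm"` draws the period histogram (frequency of monomer repeat
#' periods); `which = "md"` the monomer-distance scatter (enumeration vs
#' period), where HOR arrays appear as dense horizontal segments;
#' `which = "both"` draws the two side by side.
#'
#' @param x a `grm_hor` object.
#' @param which `"both"`, `"grm"` or `"md"`.
#' @param ... passed to the underlying plot calls.
#' @return `x`, invisibly.
#' @method plot grm_hor
#' @export
plot.grm_hor <- function(x, which = c("both", "grm", "md"), ...) {
  which <- match.arg(which)
  if (which == "both") {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  if (which %in% c("both", "grm")) {
    if (nrow(x$grm)) {
      graphics::plot(x$grm$period, x$grm$count, type = "h", lwd = 3,
                     xlab = "GRM period (monomer units)", ylab = "frequency",
                     main = "GRM diagram", ...)
    } else {
      graphics::plot.new(); graphics::title("GRM diagram (empty)")
    }
  }
  if (which %in% c("both", "md")) {
    if (nrow(x$md_points)) {
      graphics::plot(x$md_points$index, x$md_points$period, pch = 16,
                     cex = 0.4, xlab = "monomer enumeration",
                     ylab = "period (monomer units)", main = "MD diagram", ...)
    } else {
      graphics::plot.new(); graphics::title("MD diagram (empty)")
    }
  }
  invisible(x)
}

#' Write all analysis artifacts of a `grm_hor` object
#'
#' Emits the families TSV, family consensus FASTA, MD points TSV, GRM TSV,
#' segments TSV, per-array aligned scheme text and scheme TSV, and a JSON
#' summary, into `dir`.
#'
#' @param x a `grm_hor` object.
#' @param dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
write_grm_hor <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  if (!is.null(x$families)) {
    paths["families"] <- write_families_tsv(x$families, file.path(dir, "families.tsv"))
    paths["consensus"] <- write_family_consensus_fasta(x$families, file.path(dir, "family_consensus.fa"))
  }
  paths["md_points"] <- write_md_points_tsv(x$md_points, file.path(dir, "md_points.tsv"))
  paths["grm"] <- write_grm_tsv(x$grm, file.path(dir, "grm.tsv"))
  paths["segments"] <- write_segments_tsv(x$segments, file.path(dir, "segments.tsv"))
  arr <- x$arrays
  arr$start <- arr$start + 1L  # 1-based inclusive for human-readable output
  paths["arrays"] <- write_tsv(arr, file.path(dir, "arrays.tsv"))
  summary_list <- list(
    n_monomers = nrow(x$monomers),
    n_families = if (is.null(x$families)) 0L else x$families$k,
    n_md_points = nrow(x$md_points),
    arrays = lapply(x$schemes, function(sc) {
      list(array_id = sc$array_id, hor_period = sc$unit$n, tau = sc$unit$tau,
           kind = if (sc$unit$tau < sc$unit$n) "cascading" else "willard",
           canonical_unit = fmt_family(sc$unit$type_sequence),
           n_copies = sc$summary$n_copies,
           n_canonical = sc$summary$n_canonical,
           n_variant = sc$summary$n_variant,
           pct_canonical = sc$summary$pct_canonical,
           variant_runs = sc$summary$variant_runs)
    }))
  for (sc in x$schemes) {
    lines <- format_cascade_scheme(sc$copies, sc$unit, sc$start_bp)
    paths[sprintf("scheme_%d_txt", sc$array_id)] <-
      write_scheme_text(lines, file.path(dir, sprintf("scheme_array%d.txt", sc$array_id)))
    paths[sprintf("scheme_%d_tsv", sc$array_id)] <-
      write_scheme_tsv(sc$copies, file.path(dir, sprintf("scheme_array%d.tsv", sc$array_id)),
                       start_bp = sc$start_bp)
  }
  jsonlite::write_json(summary_list, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths["summary"] <- file.path(dir, "summary.json")
  invisible(paths)
}
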