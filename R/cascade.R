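#' Split monomers into tandemly organized array segments
#'
#' A satellite array is a maximal run of consecutively enumerated monomers
#' on one sequence whose genomic gaps (next start minus previous end) never
#' exceed `max_gap_bp`. Each array is annotated with its HOR period and
#' subfragment periods, obtained by running the MD/GRM machinery
#' ([compute_md_points()], [detect_segments()], [classify_segments()]) on
#' the array's own label subsequence.
#'
#' @param monomers `hor_monomers` data frame.
#' @param labels family labels aligned with `monomers` (or `hor_families`).
#' @param max_gap_bp largest intra-array genomic gap in bp; default 2000
#'   (about eleven monomer lengths).
#' @param max_period,min_support,max_gap passed to the periodicity layer.
#' @return `data.frame` with one row per array: `array_id`, `chrom`,
#'   `first_index`, `last_index`, `n_monomers`, `start`, `end` (bp, 0-based
#'   half-open), `hor_period` (NA when no segment reaches `min_support`),
#'   and `subfragment_periods` (list column).
#' @export
segment_arrays <- function(monomers, labels, max_gap_bp = 2000,
                           max_period = 50, min_support = 10, max_gap = NULL) {
  labels <- as_label_vector(labels)
  n <- nrow(monomers)
  if (n == 0) {
    return(data.frame(array_id = integer(0), chrom = character(0),
                      first_index = integer(0), last_index = integer(0),
                      n_monomers = integer(0), start = integer(0),
                      end = integer(0), hor_period = integer(0)))
  }
  stopifnot(length(labels) == n)
  new_array <- c(TRUE, monomers$chrom[-1] != monomers$chrom[-n] |
                   monomers$start[-1] - monomers$end[-n] > max_gap_bp)
  grp <- cumsum(new_array)
  out <- lapply(split(seq_len(n), grp), function(ix) {
    labs <- labels[ix]
    segs <- classify_segments(detect_segments(
      compute_md_points(labs, max_period = max_period),
      min_support = min_support, max_gap = max_gap))
    hors <- segs[segs$kind == "HOR", , drop = FALSE]
    hp <- if (nrow(hors)) hors$period[which.max(hors$support)] else NA_integer_
    sf <- sort(unique(segs$period[segs$kind == "subfragment"]))
    data.frame(chrom = monomers$chrom[ix[1]],
               first_index = monomers$index[ix[1]],
               last_index = monomers$index[ix[length(ix)]],
               n_monomers = length(ix),
               start = monomers$start[ix[1]],
               end = monomers$end[ix[length(ix)]],
               hor_period = hp,
               subfragment_periods = I(list(sf)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- cbind(array_id = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

#' Infer the canonical HOR unit of an array
#'
#' The canonical unit is the most frequent length-`n` substring of the
#' array's family-label sequence, counted up to cyclic rotation. The
#' reported rotation (the copy start) is the one occurring most often
#' immediately after another occurrence of the unit; ties prefer the
#' rotation seen at the array's first window, then the lexicographically
#' smallest. `tau` is the number of distinct types in the unit: `tau == n`
#' is Willard's type, `tau < n` marks a cascading HOR.
#'
#' @param labels family labels of the array, in enumeration order.
#' @param n the HOR period (from [segment_arrays()] / [classify_segments()]).
#' @return object of class `canonical_unit`: list with `type_sequence`
#'   (integer labels, length `n`), `n`, and `tau`.
#' @export
infer_canonical_unit <- function(labels, n) {
  labels <- as_label_vector(labels)
  n <- as.integer(n)
  if (length(labels) < 2L * n) {
    stop(structure(class = c("cascadeHOR_insufficient_data", "error", "condition"),
                   list(message = sprintf(
                     "array holds %d monomers; need at least 2*n = %d to infer an n=%d unit",
                     length(labels), 2L * n, n), call = sys.call(-1))))
  }
  N <- length(labels)
  wins <- lapply(seq_len(N - n + 1L), function(i) labels[i:(i + n - 1L)])
  keys <- vapply(wins, function(w) paste(min_rotation(w), collapse = "."), character(1))
  tab <- table(keys)
  cand <- names(tab)[tab == max(tab)]
  if (length(cand) > 1) {
    first_pos <- vapply(cand, function(k) min(which(keys == k)), numeric(1))
    winner <- cand[which.min(first_pos)]
  } else winner <- cand
  members <- which(keys == winner)
  in_members <- logical(length(keys))
  in_members[members] <- TRUE
  lin <- vapply(wins[members], paste, character(1), collapse = ".")
  follows_prev <- members > n & in_members[pmax(members - n, 1L)]
  fol_count <- tapply(as.integer(follows_prev), lin, sum)
  rots <- unique(lin)
  fol <- as.integer(fol_count[rots])
  is_first <- rots == lin[1]
  ord <- order(-fol, !is_first, rots)
  best <- rots[ord[1]]
  ts <- as.integer(strsplit(best, ".", fixed = TRUE)[[1]])
  structure(list(type_sequence = ts, n = n, tau = length(unique(ts))),
            class = "canonical_unit")
}

# lexicographically minimal rotation of an integer vector
min_rotation <- function(w) {
  n <- length(w)
  best <- w
  for (s in seq_len(n - 1L)) {
    r <- c(w[(s + 1L):n], w[1:s])
    for (i in seq_len(n)) {
      if (r[i] < best[i]) { best <- r; break }
      if (r[i] > best[i]) break
    }
  }
  best
}

#' @export
print.canonical_unit <- function(x, ...) {
  cat(sprintf("<canonical_unit> n = %d, tau = %d (%s)\n  %s\n", x$n, x$tau,
              if (x$tau < x$n) "cascading" else "Willard's type",
              paste(fmt_family(x$type_sequence), collapse = " ")))
  invisible(x)
}

#' Partition an array into HOR copies
#'
#' Copies are anchored at the canonical start label, scanning left to
#' right: a new copy opens at an occurrence of the unit's first type that
#' is immediately followed by the unit's second type, once the running
#' copy has already passed through the unit's final type (one full cycle
#' completed). Start-label occurrences inside a copy — those created by
#' duplicated rows, and trailing start-type doublet rows such as
#' `(t1,t16)` repeats — are thereby consumed by that copy, so cascading
#' schemes partition the way published ones do: a first-row duplication
#' stays one `15 + 15 + 2` variant of 32 monomers, and doublet-row repeats
#' stay `15 + 2 + 2` variants. Monomers before the first qualifying copy
#' start form a leading partial copy with status `variant`.
#'
#' A copy is `canonical` exactly when its label sequence equals the unit;
#' anything else — row multiplications, deletions, insertions, ragged array
#' edges — is a `variant` described by its row signature.
#'
#' @param labels family labels of the array, in enumeration order.
#' @param unit a `canonical_unit` (from [infer_canonical_unit()]).
#' @return `data.frame` of class `hor_copies` with columns `copy_id`,
#'   `from`, `to` (1-based offsets into `labels`), `n_monomers`, `status`,
#'   `signature`; the per-copy cascade layouts are in `attr(, "layouts")`.
#' @export
partition_copies <- function(labels, unit) {
  labels <- as_label_vector(labels)
  stopifnot(inherits(unit, "canonical_unit"))
  ts <- unit$type_sequence
  if (unit$n < 2) stop_param("cannot partition copies of a unit shorter than 2")
  start_lab <- ts[1]
  second_lab <- ts[2]
  final_lab <- ts[unit$n]
  N <- length(labels)
  from <- integer(0)
  cur <- 1L
  has_final <- labels[1] == final_lab
  anchored <- labels[1] == start_lab && (N < 2 || labels[2] == second_lab)
  if (N >= 3) {
    for (i in 2:(N - 1L)) {
      if (labels[i] == start_lab && labels[i + 1L] == second_lab &&
          (has_final || !anchored)) {
        from <- c(from, cur)
        cur <- i
        has_final <- FALSE
        anchored <- TRUE
      }
      if (labels[i] == final_lab) has_final <- TRUE
    }
  }
  from <- c(from, cur)
  to <- c(from[-1] - 1L, N)
  layouts <- vector("list", length(from))
  status <- character(length(from))
  sig <- character(length(from))
  for (k in seq_along(from)) {
    cl <- labels[from[k]:to[k]]
    layouts[[k]] <- cascade_layout(cl, unit)
    status[k] <- if (identical(cl, ts)) "canonical" else "variant"
    sig[k] <- layouts[[k]]$signature
  }
  out <- data.frame(copy_id = seq_along(from), from = from, to = to,
                    n_monomers = to - from + 1L, status = status,
                    signature = sig, stringsAsFactors = FALSE)
  attr(out, "layouts") <- layouts
  class(out) <- c("hor_copies", "data.frame")
  out
}

#' Cascading multi-row layout and row signature of one HOR copy
#'
#' Monomers are laid out left to right into rows aligned on the canonical
#' type ordering: each monomer sits in the column of its type (first
#' occurrence in the unit; types absent from the unit get fresh trailing
#' columns), and a new row starts whenever the next monomer's column does
#' not lie strictly to the right of the previous one. In the Willard limit
#' (`tau == n`) every canonical copy is a single row.
#'
#' The signature writes one term per row. Row lengths count as a single
#' term when the row's monomers occupy consecutive canonical-unit
#' positions; otherwise the row is a parenthesized sum of its consecutive
#' position runs (each monomer taking the unit position of its type that
#' maximizes the run). Rows are joined with `" + "`, except directly after
#' a parenthesized row where the join is a bare `"+"` — e.g. `"15 + 2"`,
#' `"15 + 15 + 2"`, `"(6 + 4)+2"`.
#'
#' @param copy_labels integer label sequence of the copy.
#' @param unit a `canonical_unit`.
#' @return list with `rows` (list of integer label vectors), `columns`
#'   (list of integer column vectors, same shape), `runs` (list of integer
#'   run-length vectors), and `signature` (character).
#' @export
cascade_layout <- function(copy_labels, unit) {
  copy_labels <- as_label_vector(copy_labels)
  ts <- unit$type_sequence
  type_order <- unique(ts)
  extra <- setdiff(unique(copy_labels), type_order)
  col_of <- function(lab) {
    i <- match(lab, type_order)
    ifelse(is.na(i), length(type_order) + match(lab, extra), i)
  }
  cols <- col_of(copy_labels)
  rows <- list(); row_cols <- list()
  cur <- integer(0); curc <- integer(0)
  for (i in seq_along(copy_labels)) {
    if (length(cur) && cols[i] <= curc[length(curc)]) {
      rows[[length(rows) + 1L]] <- cur
      row_cols[[length(row_cols) + 1L]] <- curc
      cur <- integer(0); curc <- integer(0)
    }
    cur <- c(cur, copy_labels[i])
    curc <- c(curc, cols[i])
  }
  rows[[length(rows) + 1L]] <- cur
  row_cols[[length(row_cols) + 1L]] <- curc
  runs <- lapply(rows, function(r) position_runs(r, ts))
  parts <- vapply(runs, function(r) {
    if (length(r) == 1) as.character(r)
    else paste0("(", paste(r, collapse = " + "), ")")
  }, character(1))
  sig <- parts[1]
  if (length(parts) > 1) {
    for (k in 2:length(parts)) {
      sep <- if (startsWith(parts[k - 1], "(")) "+" else " + "
      sig <- paste0(sig, sep, parts[k])
    }
  }
  list(rows = rows, columns = row_cols, runs = runs, signature = sig)
}

# Lengths of maximal runs of consecutive canonical-unit positions within a
# row. Each monomer may map to any unit position of its type; at each run
# start the position maximizing the chain length is chosen (ties: smallest).
position_runs <- function(row_labels, type_sequence) {
  pos_list <- lapply(row_labels, function(l) which(type_sequence == l))
  n <- length(pos_list)
  runs <- integer(0)
  i <- 1L
  while (i <= n) {
    P <- pos_list[[i]]
    if (!length(P)) { runs <- c(runs, 1L); i <- i + 1L; next }
    best_len <- 1L
    for (q in P) {
      len <- 1L; p <- q; j <- i + 1L
      while (j <= n && (p + 1L) %in% pos_list[[j]]) {
        p <- p + 1L; len <- len + 1L; j <- j + 1L
      }
      if (len > best_len) best_len <- len
    }
    runs <- c(runs, best_len)
    i <- i + best_len
  }
  runs
}

#' Summarize copy composition of a HOR array
#'
#' @param copies an `hor_copies` data frame from [partition_copies()].
#' @return list with `n_copies`, `n_canonical`, `n_variant`,
#'   `pct_canonical` (percentage of canonical copies, rounded to the
#'   nearest integer), and `variant_runs` (lengths of maximal runs of
#'   consecutive variant copies, longest first).
#' @export
summarize_array <- function(copies) {
  n <- nrow(copies)
  ncan <- sum(copies$status == "canonical")
  r <- rle(copies$status)
  vruns <- sort(r$lengths[r$values == "variant"], decreasing = TRUE)
  list(n_copies = n, n_canonical = ncan, n_variant = n - ncan,
       pct_canonical = if (n) as.integer(round(100 * ncan / n)) else NA_integer_,
       variant_runs = as.integer(vruns))
}

#' Render a cascading aligned scheme as text
#'
#' One line per cascade row; the first row of each copy is prefixed with
#' the 1-based genomic start of the copy's first monomer. Cells are the
#' type names, vertically aligned by canonical type column.
#'
#' @param copies `hor_copies` from [partition_copies()].
#' @param unit the `canonical_unit` used for partitioning.
#' @param start_bp integer vector of 0-based genomic start positions for
#'   the same monomers `copies` was computed from (optional; offsets are
#'   used when missing).
#' @return character vector of scheme lines.
#' @export
format_cascade_scheme <- function(copies, unit, start_bp = NULL) {
  layouts <- attr(copies, "layouts")
  cellw <- max(nchar(fmt_family(unique(c(unlist(lapply(layouts, function(l) unlist(l$rows))),
                                         unit$type_sequence))))) + 2L
  pos <- function(k) {
    if (is.null(start_bp)) copies$from[k] else start_bp[copies$from[k]] + 1L
  }
  posw <- max(nchar(vapply(seq_len(nrow(copies)), function(k) as.character(pos(k)), character(1)))) + 2L
  lines <- character(0)
  for (k in seq_len(nrow(copies))) {
    lay <- layouts[[k]]
    for (r in seq_along(lay$rows)) {
      prefix <- if (r == 1) formatC(pos(k), width = posw - 2L) else
        strrep(" ", posw - 2L)
      maxcol <- max(lay$columns[[r]])
      line <- rep(strrep(" ", cellw), maxcol)
      for (j in seq_along(lay$rows[[r]])) {
        cell <- fmt_family(lay$rows[[r]][j])
        line[lay$columns[[r]][j]] <- formatC(cell, width = -cellw)
      }
      lines <- c(lines, sprintf("%s  %s", prefix,
                                sub("\\s+$", "", paste(line, collapse = ""))))
    }
  }
  lines
}

#' Write scheme artifacts
#'
#' `write_scheme_text()` writes the plain-text aligned scheme;
#' `write_scheme_tsv()` one row per copy (`copy_id`, `start_bp` 1-based,
#' `n_monomers`, `status`, `signature`).
#'
#' @param lines character vector from [format_cascade_scheme()].
#' @param copies `hor_copies` data frame.
#' @param start_bp 0-based genomic starts of the array's monomers.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scheme_text <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}

#' @rdname write_scheme_text
#' @export
write_scheme_tsv <- function(copies, path, start_bp = NULL) {
  df <- data.frame(copy_id = copies$copy_id,
                   start_bp = if (is.null(start_bp)) copies$from else
                     start_bp[copies$from] + 1L,
                   n_monomers = copies$n_monomers,
                   status = copies$status,
                   signature = copies$signature)
  write_tsv(df, path)
}
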