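#' Generate a library of divergent monomer type seeds
#'
#' Produces `k` seed sequences emulating alpha-satellite monomer types: all
#' descend from one random AT-rich ancestor, mutated so that pairwise
#' divergence concentrates around `inter_type_div` (types within a real HOR
#' copy diverge roughly 20-40%). Construction is verified: any pair below
#' `0.8 * inter_type_div` is resampled.
#'
#' @param k number of types (>= 1).
#' @param monomer_len seed length in bp (default 171).
#' @param inter_type_div target pairwise divergence (default 0.25); values
#'   above 0.75 are unattainable for DNA and raise a parameter error.
#' @param seed integer seed; the same seed always yields the same library.
#' @param ancestor optional ancestor sequence to derive the types from
#'   (default: a fresh random AT-rich sequence). Sharing one ancestor across
#'   libraries emulates satellite arrays of one superfamily, all detectable
#'   with a single consensus query.
#' @return character vector of `k` sequences, with the ancestor consensus in
#'   `attr(, "ancestor")` (a natural scan query for arrays built from this
#'   library).
#' @export
make_type_library <- function(k, monomer_len = 171, inter_type_div = 0.25,
                              seed = NULL, ancestor = NULL) {
  if (k < 1) stop_param("k must be >= 1")
  if (inter_type_div > 0.75) stop_param("inter_type_div above 0.75 is infeasible for DNA")
  with_seed(seed, {
    if (is.null(ancestor)) ancestor <- random_dna(monomer_len, at = 0.6)
    stopifnot(nchar(ancestor) == monomer_len)
    # per-type substitution rate r so two types differ at ~ 2r - (4/3) r^2
    r <- if (inter_type_div > 0) 3 * (2 - sqrt(4 - 16 * inter_type_div / 3)) / 8 else 0
    types <- vapply(seq_len(k), function(i) mutate_seq(ancestor, r), character(1))
    if (k > 1) {
      for (iter in seq_len(200)) {
        d <- build_divergence_matrix(types)
        diag(d) <- Inf
        bad <- which(apply(d, 1, min) < 0.8 * inter_type_div)
        if (!length(bad)) break
        types[bad[1]] <- mutate_seq(ancestor, r)
      }
      d <- build_divergence_matrix(types)
      diag(d) <- Inf
      if (min(d) < 0.8 * inter_type_div) {
        stop_param("could not construct a type library at the requested divergence")
      }
    }
    structure(types, ancestor = ancestor)
  })
}

# i.i.d. substitutions at rate m; optionally 10% of mutation events become
# single-base indels (half insertions, half deletions).
mutate_seq <- function(s, m, indels = FALSE) {
  if (m <= 0) return(s)
  ch <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(ch)) < m)
  if (!length(hit)) return(s)
  kind <- if (indels) {
    ifelse(stats::runif(length(hit)) < 0.1,
           ifelse(stats::runif(length(hit)) < 0.5, "ins", "del"), "sub")
  } else rep("sub", length(hit))
  for (j in seq_along(hit)) {
    i <- hit[j]
    if (kind[j] == "sub") {
      ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1)
    } else if (kind[j] == "ins") {
      ch[i] <- paste0(sample(DNA_BASES, 1), ch[i])
    } else {
      ch[i] <- ""
    }
  }
  paste(ch, collapse = "")
}

#' Specify a synthetic HOR array
#'
#' Bundles and validates all parameters of a simulated tandem satellite
#' array: the monomer type library, the canonical unit grammar (types may
#' repeat, giving a cascading HOR), the number of tandem copies, mutation
#' layers, variant events, strand, and flanks. The seed fully determines
#' the output of [build_array()].
#'
#' Variant events are lists with a `copy` index and an `event`:
#' * `list(copy = 7, event = "duplicate_row", row = 1, times = 2)` —
#'   replace cascade row `row` of that copy with `times` tandem copies of
#'   itself (the classic first-row multiplication variant);
#' * `list(copy = 3, event = "delete_types", types = c(6, 7))` — drop all
#'   monomers of the given types from that copy;
#' * `list(copy = 5, event = "insert_row", labels = c(1, 16), at = 2)` —
#'   insert the given labels as an extra row before row `at`.
#'
#' @param unit integer vector of type labels forming the canonical copy
#'   (e.g. `c(1:15, 1, 16)` for the cascading 17mer; `1:10` for a Willard
#'   10mer).
#' @param n_copies number of tandem copies.
#' @param n_types number of types in the library; default `max(unit)`.
#' @param monomer_len,inter_type_div passed to [make_type_library()].
#' @param per_base_mutation per-base substitution rate applied independently
#'   to every monomer copy (HOR copies diverge by less than 5%, so sensible
#'   values satisfy `2 * per_base_mutation < 0.05`).
#' @param variant_events list of event specifications (see Details).
#' @param strand `"+"` or `"-"`; `"-"` reverse-complements the whole array.
#' @param flank_len length of the random non-repetitive flank on each side.
#' @param indels if `TRUE`, 10% of mutation events are single-base indels.
#' @param seed integer seed (required; output is a pure function of the spec).
#' @param ancestor optional shared ancestor sequence for the type library
#'   (see [make_type_library()]); used by [build_chromosome()] so that one
#'   query detects every array.
#' @return object of class `hor_array_spec`.
#' @export
hor_array_spec <- function(unit, n_copies, n_types = max(unit),
                           monomer_len = 171, inter_type_div = 0.25,
                           per_base_mutation = 0.01, variant_events = list(),
                           strand = c("+", "-"), flank_len = 500,
                           indels = FALSE, seed = 1, ancestor = NULL) {
  strand <- match.arg(strand)
  unit <- as.integer(unit)
  if (any(unit < 1) || any(unit > n_types)) stop_param("unit labels must lie in 1..n_types")
  if (n_copies < 1) stop_param("n_copies must be >= 1")
  if (per_base_mutation < 0 || per_base_mutation >= 0.5) stop_param("invalid mutation rate")
  for (ev in variant_events) {
    if (!is.list(ev) || is.null(ev$copy) || is.null(ev$event)) {
      stop_param("each variant event needs 'copy' and 'event' fields")
    }
    if (!ev$event %in% c("duplicate_row", "delete_types", "insert_row")) {
      stop_param(sprintf("unknown variant event '%s'", ev$event))
    }
    if (ev$copy < 1 || ev$copy > n_copies) stop_param("variant event copy index out of range")
  }
  structure(list(unit = unit, n_copies = as.integer(n_copies),
                 n_types = as.integer(n_types),
                 monomer_len = as.integer(monomer_len),
                 inter_type_div = inter_type_div,
                 per_base_mutation = per_base_mutation,
                 variant_events = variant_events, strand = strand,
                 flank_len = as.integer(flank_len), indels = isTRUE(indels),
                 seed = as.integer(seed), ancestor = ancestor),
            class = "hor_array_spec")
}

#' Build a synthetic satellite array with ground truth
#'
#' Materializes an [hor_array_spec()]: generates the type library, applies
#' the variant events to the per-copy label grammar, mutates every monomer
#' independently, adds random flanks, and optionally reverse-complements
#' the array. Ground truth is machine-readable: per-monomer coordinates,
#' strand, type and generating copy, plus per-copy status and row
#' signature (computed on the true label sequence with the package's own
#' partition/layout semantics, which are themselves pinned by unit tests).
#'
#' @param spec an `hor_array_spec` (or arguments forwarded to it).
#' @param chrom name of the simulated sequence.
#' @return object of class `hor_array_sim`: list with `sequence` (named
#'   character), `monomers` (truth data frame with 0-based half-open
#'   coordinates), `copies` (truth data frame), `unit`
#'   (`canonical_unit`), `types`, `query` (ancestor consensus), `spec`.
#' @export
build_array <- function(spec, chrom = "sim1") {
  stopifnot(inherits(spec, "hor_array_spec"))
  with_seed(spec$seed, {
    types <- make_type_library(spec$n_types, spec$monomer_len,
                               spec$inter_type_div, seed = NULL,
                               ancestor = spec$ancestor)
    unit_obj <- structure(list(type_sequence = spec$unit,
                               n = length(spec$unit),
                               tau = length(unique(spec$unit))),
                          class = "canonical_unit")
    base_rows <- cascade_layout(spec$unit, unit_obj)$rows
    labels <- integer(0)
    gen_copy <- integer(0)
    for (cc in seq_len(spec$n_copies)) {
      rows <- base_rows
      for (ev in spec$variant_events) {
        if (ev$copy != cc) next
        rows <- apply_variant_event(rows, ev)
      }
      cl <- unlist(rows)
      labels <- c(labels, cl)
      gen_copy <- c(gen_copy, rep(cc, length(cl)))
    }
    # Guaranteed-recovery construction: a monomer drawn from the far tail
    # of the mutation distribution can exceed the 5% family threshold to
    # every sibling, in which case no threshold clustering can recover the
    # truth. Like the type library, fixtures are verified by construction:
    # monomers realizing more than ~2.4x the expected load (cap 0.024, so
    # that intra-type pairs stay below 2 * 0.024 < 0.05 when m <= 1%) are
    # resampled.
    div_cap <- if (spec$per_base_mutation > 0)
      max(0.024, 2.4 * spec$per_base_mutation) else Inf
    seqs <- vapply(labels, function(l) {
      sq <- mutate_seq(types[[l]], spec$per_base_mutation, spec$indels)
      for (try in seq_len(50)) {
        if (.edit_distance_cpp(sq, types[[l]]) /
            max(nchar(sq), nchar(types[[l]])) <= div_cap) break
        sq <- mutate_seq(types[[l]], spec$per_base_mutation, spec$indels)
      }
      sq
    }, character(1))
    if (spec$strand == "-") {
      # the array reads in unit order on the minus strand: genome order is
      # reversed and each monomer reverse-complemented
      seqs <- rev(revcomp(seqs))
      labels <- rev(labels)
      gen_copy <- rev(gen_copy)
    }
    lens <- nchar(seqs)
    flank5 <- random_dna(spec$flank_len)
    flank3 <- random_dna(spec$flank_len)
    starts <- spec$flank_len + c(0L, cumsum(lens))[seq_along(lens)]
    monomers <- data.frame(chrom = chrom, start = as.integer(starts),
                           end = as.integer(starts + lens),
                           strand = spec$strand, type = labels,
                           gen_copy = gen_copy, stringsAsFactors = FALSE)
    sequence <- paste0(flank5, paste(seqs, collapse = ""), flank3)
    names(sequence) <- chrom
    # per-copy truth in unit orientation
    truth_labels <- if (spec$strand == "-") rev(labels) else labels
    copies_df <- as.data.frame(partition_copies(truth_labels, unit_obj))
    structure(list(sequence = sequence, monomers = monomers,
                   copies = copies_df, unit = unit_obj, types = types,
                   query = attr(types, "ancestor"), spec = spec),
              class = "hor_array_sim")
  })
}

apply_variant_event <- function(rows, ev) {
  if (ev$event == "duplicate_row") {
    r <- if (is.null(ev$row)) 1L else as.integer(ev$row)
    times <- if (is.null(ev$times)) 2L else as.integer(ev$times)
    if (r < 1 || r > length(rows)) stop_param("duplicate_row: row out of range")
    rows <- append(rows[-r], rep(rows[r], times), after = r - 1L)
  } else if (ev$event == "delete_types") {
    rows <- lapply(rows, function(rr) rr[!rr %in% ev$types])
    rows <- rows[vapply(rows, length, integer(1)) > 0]
  } else if (ev$event == "insert_row") {
    at <- if (is.null(ev$at)) 2L else as.integer(ev$at)
    rows <- append(rows, list(as.integer(ev$labels)), after = at - 1L)
  }
  rows
}

#' @export
print.hor_array_sim <- function(x, ...) {
  cat(sprintf("<hor_array_sim> %d bp, %d monomers (%d types), %d copies, strand %s\n",
              nchar(x$sequence), nrow(x$monomers), length(x$types),
              x$spec$n_copies, x$spec$strand))
  print(x$unit)
  invisible(x)
}

#' Build a synthetic chromosome from several arrays
#'
#' Concatenates independently generated arrays (e.g. a cascading 17mer and
#' a Willard 10mer) separated by random unique inserts, emulating a
#' centromeric region with multiple HOR arrays.
#'
#' @param specs list of `hor_array_spec` objects; each array draws its own
#'   independent type library.
#' @param gap_len length of the unique insert between consecutive arrays.
#' @param chrom sequence name.
#' @param seed integer seed governing the gap sequences (array seeds live
#'   in their specs).
#' @return object of class `hor_chromosome_sim`: list with `sequence`,
#'   `monomers` (with an `array_id` column), `arrays` (the individual
#'   `hor_array_sim` objects), `query` (the first array's ancestor —
#'   suitable when all arrays share `monomer_len`).
#' @export
build_chromosome <- function(specs, gap_len = 10000, chrom = "sim1", seed = 1) {
  lens <- unique(vapply(specs, function(sp) sp$monomer_len, integer(1)))
  if (length(lens) != 1) stop_param("arrays of one chromosome must share monomer_len")
  ancestor <- with_seed(seed, random_dna(lens, at = 0.6))
  specs <- lapply(specs, function(sp) { sp$ancestor <- ancestor; sp })
  sims <- lapply(specs, build_array, chrom = chrom)
  with_seed(seed + 1L, {
    pieces <- character(0)
    offset <- 0L
    mono <- list()
    for (i in seq_along(sims)) {
      s <- unname(sims[[i]]$sequence)
      m <- sims[[i]]$monomers
      m$start <- m$start + offset
      m$end <- m$end + offset
      m$array_id <- i
      m$type <- paste0(i, ":", m$type)  # types are library-local
      mono[[i]] <- m
      pieces <- c(pieces, s)
      offset <- offset + nchar(s)
      if (i < length(sims)) {
        gp <- random_dna(gap_len)
        pieces <- c(pieces, gp)
        offset <- offset + gap_len
      }
    }
    sequence <- paste(pieces, collapse = "")
    names(sequence) <- chrom
    structure(list(sequence = sequence, monomers = do.call(rbind, mono),
                   arrays = sims, query = ancestor),
              class = "hor_chromosome_sim")
  })
}

#' Write simulation artifacts
#'
#' Writes the simulated sequence as FASTA, the per-monomer truth as BED
#' (name = `t<type>`, score = generating copy) plus a TSV with full truth
#' columns, the per-copy truth TSV, and the spec as JSON.
#'
#' @param sim an `hor_array_sim`.
#' @param dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "array.fa")
  ss <- Biostrings::DNAStringSet(unname(sim$sequence))
  names(ss) <- names(sim$sequence)
  Biostrings::writeXStringSet(ss, fa, width = 80L)
  qfa <- file.path(dir, "query.fa")
  qq <- Biostrings::DNAStringSet(sim$query)
  names(qq) <- "ancestor_consensus"
  Biostrings::writeXStringSet(qq, qfa, width = 80L)
  bed <- file.path(dir, "truth_monomers.bed")
  bdf <- data.frame(chrom = sim$monomers$chrom, start = sim$monomers$start,
                    end = sim$monomers$end, name = fmt_family(sim$monomers$type),
                    score = sim$monomers$gen_copy, strand = sim$monomers$strand)
  con <- file(bed, open = "wb")
  write.table(bdf, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, eol = "\n")
  close(con)
  mtsv <- file.path(dir, "truth_monomers.tsv")
  write_tsv(sim$monomers, mtsv)
  ctsv <- file.path(dir, "truth_copies.tsv")
  write_tsv(sim$copies, ctsv)
  spec <- file.path(dir, "spec.json")
  write_array_spec(sim$spec, spec)
  invisible(c(fasta = fa, query = qfa, bed = bed, monomers = mtsv,
              copies = ctsv, spec = spec))
}

#' Serialize an array spec to JSON and back
#'
#' @param spec an `hor_array_spec`.
#' @param path JSON file.
#' @return `path` / the restored `hor_array_spec`.
#' @export
write_array_spec <- function(spec, path) {
  x <- unclass(spec)
  x <- x[!vapply(x, is.null, logical(1))]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_array_spec
#' @export
read_array_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  ev <- x$variant_events
  if (is.null(ev)) ev <- list()
  hor_array_spec(unit = x$unit, n_copies = x$n_copies, n_types = x$n_types,
                 monomer_len = x$monomer_len,
                 inter_type_div = x$inter_type_div,
                 per_base_mutation = x$per_base_mutation,
                 variant_events = ev, strand = x$strand,
                 flank_len = x$flank_len, indels = x$indels, seed = x$seed,
                 ancestor = if (is.character(x$ancestor) && nzchar(x$ancestor))
                   x$ancestor else NULL)
}
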