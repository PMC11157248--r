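#' Scan genomic sequence for satellite monomers matching a consensus
#'
#' Finds all non-overlapping occurrences of an alpha-satellite (or other
#' tandem repeat) consensus `query` in `subject`, on both strands, by
#' semi-global edit-distance alignment: every accepted hit is a subject
#' substring whose divergence to the query (edit distance over the longer
#' length) is at most `max_div`. Candidate alignments are collected from both
#' orientations, sorted by divergence (ties: leftmost start, then `+` strand)
#' and greedily accepted if they do not overlap a previously accepted hit,
#' which reproduces the tandem tiling of satellite arrays deterministically.
#' Accepted monomers are sorted by position and enumerated `0..N-1` in order
#' of appearance.
#'
#' @param subject subject sequence(s): FASTA path, named character vector, or
#'   `DNAStringSet`. Multiple sequences are scanned in order and share one
#'   global enumeration.
#' @param query consensus query (FASTA path, string, or `DNAString`),
#'   nominally ~171 bp, at least 50 bp, alphabet `{A,C,G,T,N}`. `NULL` uses
#'   the packaged synthetic alphoid consensus (see [default_consensus()]).
#' @param max_div maximum divergence of a reported monomer to the query;
#'   must lie in (0, 0.5). Default 0.30: monomer types within one HOR copy
#'   diverge ~20-40%, so the query-to-monomer tolerance must absorb at least
#'   the intra-type half of that range.
#' @param min_len,max_len admissible monomer lengths in bp; default
#'   `0.5 * nchar(query)` and `1.5 * nchar(query)`, rejecting fragments and
#'   fused dimers.
#' @return a `data.frame` of class `hor_monomers` with columns `chrom`,
#'   `start` (0-based), `end` (exclusive), `strand`, `sequence` (oriented to
#'   the query strand), `index` (global enumeration), `div_to_query`.
#' @seealso [write_monomers_bed()], [write_monomers_fasta()], [grm_hor()]
#' @export
scan_monomers <- function(subject, query = NULL, max_div = 0.30,
                          min_len = NULL, max_len = NULL) {
  if (is.null(query)) query <- default_consensus()
  q <- as_dna_chr(query, what = "query")
  if (length(q) != 1) stop_input("query must be a single consensus sequence")
  q <- check_dna(q, what = "query")
  lq <- nchar(q)
  if (lq < 50) stop_input("query shorter than 50 bp")
  if (!is.numeric(max_div) || max_div <= 0 || max_div >= 0.5) {
    stop_param("max_div must lie strictly between 0 and 0.5")
  }
  if (is.null(min_len)) min_len <- as.integer(floor(0.5 * lq))
  if (is.null(max_len)) max_len <- as.integer(ceiling(1.5 * lq))
  if (min_len < 1 || max_len < min_len) stop_param("invalid length bounds")

  subj <- as_dna_chr(subject, what = "subject")
  res <- list()
  for (si in seq_along(subj)) {
    s <- subj[[si]]
    if (!nzchar(s)) next
    hits <- scan_one_sequence(s, q, max_div, min_len, max_len)
    if (nrow(hits)) {
      hits$chrom <- names(subj)[si]
      res[[length(res) + 1L]] <- hits
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(start = integer(0), end = integer(0), strand = character(0),
               sequence = character(0), div_to_query = numeric(0),
               chrom = character(0), stringsAsFactors = FALSE)
  out <- out[, c("chrom", "start", "end", "strand", "sequence", "div_to_query")]
  out$index <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  structure(out, class = c("hor_monomers", "data.frame"),
            query = q, max_div = max_div)
}

# Candidate alignments of the query in s, both strands, coordinates on the
# forward strand (0-based half-open).
collect_candidates <- function(s, q, max_div, min_len, max_len) {
  n <- nchar(s)
  fwd <- .scan_candidates_cpp(s, q, max_div, min_len, max_len, 2L)
  rev <- .scan_candidates_cpp(revcomp(s), q, max_div, min_len, max_len, 2L)
  fwd$strand <- rep("+", nrow(fwd))
  if (nrow(rev)) {
    tmp <- rev$start
    rev$start <- n - rev$end
    rev$end <- n - tmp
  }
  rev$strand <- rep("-", nrow(rev))
  rbind(fwd, rev)
}

# Greedy best-first selection into an occupancy mask: edit distance, then
# length closest to the query, then leftmost start, then + strand.
greedy_accept <- function(cand, occupied, lq) {
  if (!nrow(cand)) return(list(accepted = cand, occupied = occupied))
  ord <- order(cand$ed, abs(cand$end - cand$start - lq), cand$start,
               cand$strand != "+")
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    a <- cand$start[i] + 1L
    b <- cand$end[i]
    if (!any(occupied[a:b])) {
      occupied[a:b] <- TRUE
      keep[i] <- TRUE
    }
  }
  list(accepted = cand[keep, , drop = FALSE], occupied = occupied)
}

# Scan one subject string on both strands. After the first greedy pass,
# uncovered intervals long enough to hold a monomer are rescanned in
# isolation (recursively, via the same candidate machinery), so tandem
# arrays tile completely even when edit-distance plateaus jitter the
# boundary of a neighbouring hit.
scan_one_sequence <- function(s, q, max_div, min_len, max_len) {
  n <- nchar(s)
  lq <- nchar(q)
  sel <- greedy_accept(collect_candidates(s, q, max_div, min_len, max_len),
                       logical(n), lq)
  acc <- sel$accepted
  occupied <- sel$occupied
  for (pass in 1:10) {
    r <- rle(occupied)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gaps <- which(!r$values & r$lengths >= min_len)
    added <- FALSE
    for (g in gaps) {
      sub <- substr(s, starts[g], ends[g])
      cand <- collect_candidates(sub, q, max_div, min_len, max_len)
      if (!nrow(cand)) next
      cand$start <- cand$start + starts[g] - 1L
      cand$end <- cand$end + starts[g] - 1L
      got <- greedy_accept(cand, occupied, lq)
      if (nrow(got$accepted)) {
        acc <- rbind(acc, got$accepted)
        occupied <- got$occupied
        added <- TRUE
      }
    }
    if (!added) break
  }
  # Local repair: a hole too small to hold a monomer, sitting next to a
  # poor hit, usually means the poor hit is a truncated alignment that
  # crowded out the real one. Drop the worse neighbour and rescan the
  # merged window; keep the replacement when it aligns better.
  if (nrow(acc)) {
    r <- rle(occupied)
    rends <- cumsum(r$lengths)
    rstarts <- rends - r$lengths + 1L
    holes <- which(!r$values & r$lengths >= 5L & r$lengths < min_len)
    for (h in holes) {
      hs <- rstarts[h]; he <- rends[h]
      nb <- which(acc$end == hs - 1L | acc$start == he)
      if (!length(nb)) next
      for (i in nb[order(-acc$div[nb])]) {
        w0 <- min(acc$start[i], hs - 1L)
        w1 <- max(acc$end[i], he)
        sub <- substr(s, w0 + 1L, w1)
        cand <- collect_candidates(sub, q, max_div, min_len, max_len)
        if (!nrow(cand)) next
        cand$start <- cand$start + w0
        cand$end <- cand$end + w0
        occ2 <- occupied
        occ2[(acc$start[i] + 1L):acc$end[i]] <- FALSE
        got <- greedy_accept(cand, occ2, lq)
        if (nrow(got$accepted) && min(got$accepted$div) < acc$div[i] - 1e-9) {
          acc <- rbind(acc[-i, , drop = FALSE], got$accepted)
          occupied <- got$occupied
          break
        }
      }
    }
  }
  if (!nrow(acc)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), sequence = character(0),
                      div_to_query = numeric(0), stringsAsFactors = FALSE))
  }
  acc <- acc[order(acc$start), , drop = FALSE]
  acc <- polish_boundaries(acc, s, q, max_div, min_len)
  seqs <- substring(s, acc$start + 1L, acc$end)
  flip <- acc$strand == "-"
  if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
  data.frame(start = as.integer(acc$start), end = as.integer(acc$end),
             strand = acc$strand, sequence = seqs, div_to_query = acc$div,
             stringsAsFactors = FALSE)
}

# Boundary polish: where adjacent same-strand hits deviate from the query
# length (or leave a tiny gap), re-optimize the cut position between them,
# minimizing total edit distance to the query and, on ties, the deviation
# of both lengths from the query length. Alignment-score plateaus otherwise
# leave +-1-2 bp jitter on tandem boundaries, which inflates within-family
# divergence at higher mutation rates.
polish_boundaries <- function(acc, s, q, max_div, min_len) {
  n <- nrow(acc)
  if (n < 2) return(acc)
  lq <- nchar(q)
  for (i in seq_len(n - 1L)) {
    gap <- acc$start[i + 1L] - acc$end[i]
    if (gap < 0 || gap > 3L) next
    if (acc$strand[i] != acc$strand[i + 1L]) next
    lenL <- acc$end[i] - acc$start[i]
    lenR <- acc$end[i + 1L] - acc$start[i + 1L]
    if (gap == 0L && lenL == lq && lenR == lq) next
    ls <- acc$start[i]
    re <- acc$end[i + 1L]
    b0 <- acc$end[i]
    cuts <- seq.int(max(ls + min_len, b0 - 6L), min(re - min_len, b0 + gap + 6L))
    if (!length(cuts)) next
    minus <- acc$strand[i] == "-"
    best <- NULL
    for (cpos in cuts) {
      sL <- substr(s, ls + 1L, cpos)
      sR <- substr(s, cpos + 1L, re)
      if (minus) { sL <- revcomp(sL); sR <- revcomp(sR) }
      edL <- .edit_distance_cpp(sL, q)
      edR <- .edit_distance_cpp(sR, q)
      dvL <- edL / max(lq, nchar(sL))
      dvR <- edR / max(lq, nchar(sR))
      if (dvL > max_div || dvR > max_div) next
      score <- c(edL + edR, abs(nchar(sL) - lq) + abs(nchar(sR) - lq))
      if (is.null(best) || score[1] < best$score[1] ||
          (score[1] == best$score[1] && score[2] < best$score[2])) {
        best <- list(score = score, cut = cpos, edL = edL, edR = edR,
                     dvL = dvL, dvR = dvR)
      }
    }
    if (is.null(best)) next
    acc$end[i] <- best$cut
    acc$start[i + 1L] <- best$cut
    acc$ed[i] <- best$edL
    acc$ed[i + 1L] <- best$edR
    acc$div[i] <- best$dvL
    acc$div[i + 1L] <- best$dvR
  }
  acc
}

#' Packaged default consensus query
#'
#' Returns the packaged 171 bp default query sequence. This is a synthetic,
#' seeded AT-rich stand-in for an alphoid consensus (see the package
#' vignette); for real analyses supply your own consensus, and for simulated
#' arrays use the simulator's ancestor consensus
#' (`build_array(...)$query`).
#'
#' @return single character string (171 bp).
#' @export
default_consensus <- function() {
  path <- system.file("extdata", "synthetic_alphoid_consensus.fa",
                      package = "cascadeHOR", mustWork = TRUE)
  unname(as_dna_chr(path))
}

#' @export
`[.hor_monomers` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) &&
      !all(c("chrom", "start", "end", "strand", "div_to_query") %in% names(out))) {
    class(out) <- "data.frame"
  }
  out
}

#' @export
print.hor_monomers <- function(x, ...) {
  cat(sprintf("<hor_monomers> %d monomers on %d sequence(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x)) {
    cat(sprintf("  lengths %d-%d bp, divergence to query %.3f-%.3f, %d on '-' strand\n",
                min(x$end - x$start), max(x$end - x$start),
                min(x$div_to_query), max(x$div_to_query), sum(x$strand == "-")))
    print(utils::head(as.data.frame(x)[, c("chrom", "start", "end", "strand", "div_to_query")], 5))
    if (nrow(x) > 5) cat(sprintf("  ... %d more\n", nrow(x) - 5L))
  }
  invisible(x)
}

#' Write monomers as BED6
#'
#' One row per monomer: `chrom, start, end, name (m<index>),
#' score = round(1000 * (1 - divergence)), strand`. Coordinates are 0-based
#' half-open, as in BED.
#'
#' @param monomers `hor_monomers` data frame from [scan_monomers()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_monomers_bed <- function(monomers, path) {
  bed <- data.frame(chrom = monomers$chrom, start = monomers$start,
                    end = monomers$end, name = sprintf("m%d", monomers$index),
                    score = round(1000 * (1 - monomers$div_to_query)),
                    strand = monomers$strand)
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(bed, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write or read monomer FASTA
#'
#' Headers follow `m<index>|<chrom>:<start+1>-<end>|<strand>` (positions
#' 1-based inclusive in the header; the in-memory representation stays
#' 0-based half-open). `read_monomers_fasta()` inverts the format so a
#' monomer set round-trips through disk.
#'
#' @param monomers `hor_monomers` data frame.
#' @param path FASTA file path.
#' @return `path` (writer) or an `hor_monomers` data frame (reader).
#' @export
write_monomers_fasta <- function(monomers, path) {
  headers <- sprintf("m%d|%s:%d-%d|%s", monomers$index, monomers$chrom,
                     monomers$start + 1L, monomers$end, monomers$strand)
  ss <- Biostrings::DNAStringSet(monomers$sequence)
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' @rdname write_monomers_fasta
#' @export
read_monomers_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) {
    out <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), sequence = character(0),
                      div_to_query = numeric(0), index = integer(0),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("hor_monomers", "data.frame")))
  }
  hdr <- names(ss)
  parts <- regmatches(hdr, regexec("^m(\\d+)\\|(.+):(\\d+)-(\\d+)\\|([+-])", hdr))
  bad <- vapply(parts, length, integer(1)) != 6
  if (any(bad)) stop_input("monomer FASTA headers do not follow m<i>|chrom:start-end|strand")
  out <- data.frame(
    chrom = vapply(parts, `[`, character(1), 3),
    start = as.integer(vapply(parts, `[`, character(1), 4)) - 1L,
    end = as.integer(vapply(parts, `[`, character(1), 5)),
    strand = vapply(parts, `[`, character(1), 6),
    sequence = toupper(as.character(ss)),
    div_to_query = NA_real_,
    index = as.integer(vapply(parts, `[`, character(1), 2)),
    stringsAsFactors = FALSE)
  out <- out[order(out$index), ]
  rownames(out) <- NULL
  structure(out, class = c("hor_monomers", "data.frame"))
}
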