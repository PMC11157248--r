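#' Normalized edit distance between two DNA sequences
#'
#' Computes the Levenshtein (unit-cost) edit distance between `a` and `b`,
#' normalized by the length of the longer sequence. The result is symmetric,
#' lies in \[0, 1\], and is 0 exactly when the sequences are identical.
#' This is the divergence measure used throughout the package: monomer
#' families are sets of monomers with pairwise divergence below 5%, and the
#' monomer scanner accepts hits whose divergence to the consensus query is
#' below `max_div`.
#'
#' `N` (and any other ambiguity code) never matches anything, including
#' another `N`, so runs of assembly gaps accumulate full mismatch cost.
#'
#' @param a,b character vectors of DNA sequences (recycled to common length).
#' @return numeric vector of divergences in \[0, 1\].
#' @examples
#' divergence("ACGTACGT", "ACGTACGT")  # 0
#' divergence("ACGT", "ACGA")          # 0.25
#' @export
divergence <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop_input("empty sequence vector")
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  if (any(!nzchar(a)) || any(!nzchar(b))) stop_input("empty sequence")
  a <- vapply(a, check_dna, character(1), what = "sequence a")
  b <- vapply(b, check_dna, character(1), what = "sequence b")
  vapply(seq_len(n), function(i) {
    .edit_distance_cpp(a[i], b[i]) / max(nchar(a[i]), nchar(b[i]))
  }, numeric(1))
}
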