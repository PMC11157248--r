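# Shared fixtures and independent oracles used across test files.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# quadratic-DP Levenshtein distance, independent of the package's C++ path
ed_oracle <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  D <- matrix(0L, n + 1, m + 1)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  if (n && m) {
    for (i in 1:n) {
      for (j in 1:m) {
        D[i + 1, j + 1] <- min(D[i, j] + (a[i] != b[j]),
                               D[i, j + 1] + 1L, D[i + 1, j] + 1L)
      }
    }
  }
  D[n + 1, m + 1]
}

div_oracle <- function(a, b) ed_oracle(a, b) / max(nchar(a), nchar(b))

# brute-force next-same-label search
md_oracle <- function(labels, max_period = 50) {
  out <- list()
  for (i in seq_along(labels)) {
    j <- i + 1L
    while (j <= length(labels) && labels[j] != labels[i]) j <- j + 1L
    if (j <= length(labels) && j - i <= max_period) {
      out[[length(out) + 1L]] <- c(i - 1L, j - i)
    }
  }
  if (!length(out)) return(data.frame(index = integer(0), period = integer(0)))
  m <- do.call(rbind, out)
  data.frame(index = m[, 1], period = m[, 2])
}

unit17 <- c(1:15, 1L, 16L)

# the cascading 36mer unit: rows of 6, 17, 8 and 5 monomers over 18 types
unit36 <- c(1L, 16L, 17L, 2L, 3L, 4L,
            1L, 16L, 17L, 2:15,
            1L, 16L, 17L, 2L, 3L, 4L, 5L, 18L,
            11:15)

as_unit <- function(ts) {
  structure(list(type_sequence = as.integer(ts), n = length(ts),
                 tau = length(unique(ts))), class = "canonical_unit")
}

sim_cascading17 <- function(n_copies, m = 0.01, seed = 1, ...) {
  build_array(hor_array_spec(unit = unit17, n_copies = n_copies,
                             per_base_mutation = m, seed = seed, ...))
}

sim_willard10 <- function(n_copies, m = 0.01, seed = 1, ...) {
  build_array(hor_array_spec(unit = 1:10, n_copies = n_copies,
                             per_base_mutation = m, seed = seed, ...))
}
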