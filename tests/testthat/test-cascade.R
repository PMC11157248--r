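u17 <- as_unit(unit17)

test_that("cascade layout reproduces the canonical 17mer two-row scheme", {
  lay <- cascade_layout(unit17, u17)
  expect_equal(lengths(lay$rows), c(15L, 2L))
  expect_identical(lay$rows[[2]], c(1L, 16L))
  # the second-row t1 is vertically aligned under the first-row t1
  expect_equal(lay$columns[[2]][1], lay$columns[[1]][1])
  expect_identical(lay$signature, "15 + 2")
})

test_that("Willard degenerate case: canonical copies are a single row", {
  u10 <- as_unit(1:10)
  lay <- cascade_layout(1:10, u10)
  expect_equal(length(lay$rows), 1L)
  expect_identical(lay$signature, "10")
})

test_that("published variant signatures are reproduced verbatim", {
  # first-row duplication (32 monomers)
  lay <- cascade_layout(c(1:15, 1:15, 1L, 16L), u17)
  expect_identical(lay$signature, "15 + 15 + 2")
  # six-fold first-row multiplication (92 monomers)
  lay92 <- cascade_layout(c(rep(1:15, 6), 1L, 16L), u17)
  expect_identical(lay92$signature,
                   "15 + 15 + 15 + 15 + 15 + 15 + 2")
  # non-contiguous row written as parenthesized runs
  lay64 <- cascade_layout(c(1:6, 12:15, 1L, 16L), u17)
  expect_identical(lay64$signature, "(6 + 4)+2")
  # doublet-row variants
  expect_identical(cascade_layout(c(1:15, 1L, 16L, 1L, 16L), u17)$signature,
                   "15 + 2 + 2")
  expect_identical(cascade_layout(c(1:6, 12:15, 1L, 16L, 1L, 16L), u17)$signature,
                   "(6 + 4)+2 + 2")
})

test_that("the canonical 36mer lays out as four rows of 6, 17, 8 and 5", {
  u36 <- as_unit(unit36)
  expect_equal(u36$n, 36L)
  expect_equal(u36$tau, 18L)
  lay <- cascade_layout(unit36, u36)
  expect_equal(lengths(lay$rows), c(6L, 17L, 8L, 5L))
  expect_identical(unlist(lay$runs), c(6L, 17L, 8L, 5L))
})

test_that("cascade layout is a pure function of labels and unit", {
  set.seed(81)
  for (i in 1:10) {
    labs <- sample(unit17, sample(5:40, 1), replace = TRUE)
    a <- cascade_layout(labs, u17)
    b <- cascade_layout(labs, u17)
    expect_identical(a, b)
    expect_identical(unlist(a$rows), labs)  # rows concatenate to the input
  }
})

test_that("canonical unit inference recovers the majority unit and rotation", {
  labs <- rep(unit17, 10)
  u <- infer_canonical_unit(labs, 17)
  expect_identical(u$type_sequence, unit17)
  expect_equal(u$tau, 16L)
  # one variant copy does not change the canonical unit
  labs2 <- c(rep(unit17, 4), c(1:15, 1:15, 1L, 16L), rep(unit17, 4))
  u2 <- infer_canonical_unit(labs2, 17)
  expect_identical(u2$type_sequence, unit17)
  # Willard case
  uw <- infer_canonical_unit(rep(1:10, 5), 10)
  expect_identical(uw$type_sequence, 1:10)
  expect_equal(uw$tau, 10L)
  expect_error(infer_canonical_unit(rep(unit17, 2)[1:20], 17),
               class = "cascadeHOR_insufficient_data")
})

test_that("copy partitioning consumes duplicated and doublet rows", {
  # pure tandem: one copy per unit
  cp <- partition_copies(rep(unit17, 10), u17)
  expect_equal(nrow(cp), 10L)
  expect_true(all(cp$status == "canonical"))
  expect_true(all(cp$signature == "15 + 2"))
  # copies 7 and 8 with duplicated first row: 32-monomer variants
  labs <- unlist(lapply(1:10, function(cc) {
    if (cc %in% c(7, 8)) c(1:15, 1:15, 1L, 16L) else unit17
  }))
  cp2 <- partition_copies(labs, u17)
  expect_equal(nrow(cp2), 10L)
  expect_identical(cp2$status, c(rep("canonical", 6), "variant", "variant",
                                 "canonical", "canonical"))
  expect_identical(cp2$n_monomers[7:8], c(32L, 32L))
  expect_identical(cp2$signature[7], "15 + 15 + 2")
  # six-fold multiplication: one 92-monomer variant
  labs3 <- c(unit17, c(rep(1:15, 6), 1L, 16L), unit17)
  cp3 <- partition_copies(labs3, u17)
  expect_equal(nrow(cp3), 3L)
  expect_identical(cp3$n_monomers, c(17L, 92L, 17L))
  expect_identical(cp3$status, c("canonical", "variant", "canonical"))
  # doublet rows stay inside their copy
  labs4 <- c(unit17, c(1:15, 1L, 16L, 1L, 16L), unit17)
  cp4 <- partition_copies(labs4, u17)
  expect_equal(nrow(cp4), 3L)
  expect_identical(cp4$signature[2], "15 + 2 + 2")
})

test_that("partitioning is complete: copies tile the label sequence", {
  set.seed(82)
  for (rep_i in 1:8) {
    n_cop <- sample(4:12, 1)
    labs <- unlist(lapply(seq_len(n_cop), function(cc) {
      r <- runif(1)
      if (r < 0.2) c(1:15, 1:15, 1L, 16L)
      else if (r < 0.35) c(1:6, 12:15, 1L, 16L)
      else unit17
    }))
    cp <- partition_copies(labs, u17)
    expect_identical(cp$from[1], 1L)
    expect_identical(cp$to[nrow(cp)], length(labs))
    expect_true(all(cp$from[-1] == cp$to[-nrow(cp)] + 1L))
  }
})

test_that("array summaries report canonical percentage and variant runs", {
  fake <- function(status) {
    data.frame(copy_id = seq_along(status), status = status)
  }
  s <- summarize_array(fake(c(rep("canonical", 94), rep("variant", 6))))
  expect_equal(s$pct_canonical, 94L)
  expect_equal(summarize_array(fake(rep("canonical", 7)))$pct_canonical, 100L)
  s2 <- summarize_array(fake(c(rep("canonical", 10), rep("variant", 5))))
  expect_true(5L %in% s2$variant_runs)
})

test_that("arrays split on large genomic gaps and chromosome changes", {
  sim <- sim_cascading17(3, m = 0, seed = 83)
  m <- scan_monomers(sim$sequence, sim$query)
  labs <- assign_families(m)
  one <- segment_arrays(m, labs, max_gap_bp = 2000)
  expect_equal(nrow(one), 1L)
  # insert a 10 kb unique spacer between two arrays
  two_seq <- paste0(sim$sequence, paste(rep("ACGT", 2500), collapse = ""),
                    sim$sequence)
  names(two_seq) <- "sim1"
  m2 <- scan_monomers(two_seq, sim$query)
  labs2 <- assign_families(m2)
  two <- segment_arrays(m2, labs2, max_gap_bp = 2000)
  expect_equal(nrow(two), 2L)
  expect_equal(two$n_monomers, rep(nrow(m), 2))
})

test_that("scheme text aligns columns and prefixes copy start positions", {
  labs <- rep(unit17, 3)
  cp <- partition_copies(labs, u17)
  start_bp <- 1000L + 171L * (seq_along(labs) - 1L)
  lines <- format_cascade_scheme(cp, u17, start_bp)
  expect_equal(length(lines), 6L)  # two rows per copy
  expect_match(lines[1], "^\\s*1001  t1\\b")
  expect_match(lines[3], sprintf("^\\s*%d  t1\\b", 1000L + 171L * 17L + 1L))
  # second row: t1 under t1, t16 at the far right
  expect_equal(regexpr("t1\\b", lines[1]), regexpr("t1\\b", lines[2]))
  expect_match(lines[2], "t16\\s*$")
})
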