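test_that("exact tandem copies are detected with zero divergence", {
  set.seed(11)
  q <- rand_dna(171)
  subj <- paste0(rand_dna(500), strrep(q, 3), rand_dna(500))
  m <- scan_monomers(subj, q)
  expect_equal(nrow(m), 3L)
  expect_true(all(m$end - m$start == 171L))
  expect_true(all(m$strand == "+"))
  expect_true(all(m$div_to_query == 0))
  expect_identical(m$index, 0:2)
  expect_identical(m$start, 500L + 171L * (0:2))
  expect_true(all(m$sequence == q))
})

test_that("reverse-complement arrays are found on the minus strand, mirrored", {
  set.seed(12)
  q <- rand_dna(171)
  flank1 <- rand_dna(400)
  flank2 <- rand_dna(450)
  subj_fwd <- paste0(flank1, strrep(q, 3), flank2)
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  subj_rev <- rc(subj_fwd)
  fwd <- scan_monomers(subj_fwd, q)
  rev <- scan_monomers(subj_rev, q)
  expect_equal(nrow(rev), 3L)
  expect_true(all(rev$strand == "-"))
  expect_true(all(rev$sequence == q))  # reported oriented to the query strand
  # coordinate mirror: start' = L - end, end' = L - start
  L <- nchar(subj_fwd)
  expect_identical(sort(rev$start), sort(L - fwd$end))
  expect_identical(sort(rev$end), sort(L - fwd$start))
})

test_that("reported divergence equals the DP oracle on mutated copies", {
  set.seed(14)
  q <- rand_dna(171)
  mut10 <- function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < 0.10)
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(ch, collapse = "")
  }
  subj <- paste0(rand_dna(300), mut10(q), mut10(q), mut10(q), rand_dna(300))
  m <- scan_monomers(subj, q)
  expect_equal(nrow(m), 3L)
  expect_true(all(m$div_to_query >= 0.06 & m$div_to_query <= 0.14))
  for (i in seq_len(nrow(m))) {
    expect_equal(m$div_to_query[i], div_oracle(m$sequence[i], q))
  }
})

test_that("monomers are non-overlapping, sorted, and re-detectable (idempotence)", {
  sim <- sim_cascading17(4, m = 0.02, seed = 21)
  m <- grm_scan_fixture <- scan_monomers(sim$sequence, sim$query)
  expect_true(all(diff(m$start) > 0))
  expect_true(all(m$end[-nrow(m)] <= m$start[-1]))
  # idempotence: each emitted monomer re-detected on its own
  for (i in sample(nrow(m), 5)) {
    hit <- scan_monomers(m$sequence[i], sim$query)
    expect_equal(nrow(hit), 1L)
    expect_lte(hit$div_to_query, 0.30)
  }
})

test_that("detected count equals ground truth on synthetic arrays", {
  for (seed in c(31, 32, 33)) {
    sim <- sim_cascading17(6, m = 0.02, seed = seed)
    m <- scan_monomers(sim$sequence, sim$query, max_div = 0.3)
    expect_equal(nrow(m), nrow(sim$monomers))
  }
  sim <- sim_willard10(8, m = 0.02, seed = 34)
  m <- scan_monomers(sim$sequence, sim$query, max_div = 0.3)
  expect_equal(nrow(m), nrow(sim$monomers))
})

test_that("scanner input validation and degenerate inputs behave as specified", {
  q <- rand_dna(171)
  expect_error(scan_monomers("ACGT", paste0(substr(q, 1, 170), "X")),
               class = "cascadeHOR_input_error")
  expect_error(scan_monomers("ACGT", q, max_div = 0.5),
               class = "cascadeHOR_param_error")
  expect_error(scan_monomers("ACGT", rand_dna(49)),
               class = "cascadeHOR_input_error")
  # empty subject: empty result, not an error
  m <- scan_monomers("", q)
  expect_s3_class(m, "hor_monomers")
  expect_equal(nrow(m), 0L)
})

test_that("monomer BED and FASTA round-trip through disk", {
  sim <- sim_cascading17(2, m = 0.01, seed = 41)
  m <- scan_monomers(sim$sequence, sim$query)
  fa <- tempfile(fileext = ".fa")
  bed <- tempfile(fileext = ".bed")
  write_monomers_fasta(m, fa)
  write_monomers_bed(m, bed)
  back <- read_monomers_fasta(fa)
  expect_identical(back$start, m$start)
  expect_identical(back$end, m$end)
  expect_identical(back$strand, m$strand)
  expect_identical(back$sequence, m$sequence)
  bedlines <- readLines(bed)
  expect_equal(length(bedlines), nrow(m))
  expect_match(bedlines[1], "^sim1\t\\d+\t\\d+\tm0\t\\d+\t\\+$")
})
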