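test_that("type libraries are seed-deterministic and sufficiently divergent", {
  lib1 <- make_type_library(16, seed = 91)
  lib2 <- make_type_library(16, seed = 91)
  expect_identical(lib1, lib2)
  expect_identical(make_type_library(1, seed = 92)[1],
                   make_type_library(1, seed = 92)[1])
  d <- build_divergence_matrix(as.character(lib1))
  diag(d) <- Inf
  expect_true(all(d >= 0.20))  # 0.8 * default 0.25
  expect_error(make_type_library(4, inter_type_div = 0.8),
               class = "cascadeHOR_param_error")
})

test_that("a single unmutated canonical copy has exact structure and coordinates", {
  spec <- hor_array_spec(unit = unit17, n_copies = 1, per_base_mutation = 0,
                         flank_len = 200, seed = 93)
  sim <- build_array(spec)
  expect_equal(unname(nchar(sim$sequence)), 17 * 171 + 400)
  expect_equal(nrow(sim$monomers), 17L)
  expect_equal(length(unique(sim$monomers$type)), 16L)
  expect_identical(sim$monomers$type, unit17)
  expect_identical(sim$monomers$start, 200L + 171L * (0:16))
  # monomer sequences equal their type seeds at zero mutation
  sub <- substring(unname(sim$sequence), sim$monomers$start + 1, sim$monomers$end)
  expect_identical(sub, unname(sim$types[sim$monomers$type]))
})

test_that("simulation is bit-identical across runs with one seed", {
  spec <- hor_array_spec(unit = unit17, n_copies = 5, seed = 94,
                         variant_events = list(list(copy = 3, event = "duplicate_row",
                                                    row = 1, times = 2)))
  s1 <- build_array(spec)
  s2 <- build_array(spec)
  expect_identical(s1$sequence, s2$sequence)
  expect_identical(s1$monomers, s2$monomers)
  expect_identical(s1$copies, s2$copies)
  s3 <- build_array(hor_array_spec(unit = unit17, n_copies = 5, seed = 95))
  expect_false(identical(unname(s1$sequence), unname(s3$sequence)))
})

test_that("variant events shape the truth copies as specified", {
  spec <- hor_array_spec(unit = unit17, n_copies = 10, seed = 96,
                         variant_events = list(
                           list(copy = 7, event = "duplicate_row", row = 1, times = 2),
                           list(copy = 8, event = "duplicate_row", row = 1, times = 6)))
  sim <- build_array(spec)
  expect_identical(sim$copies$signature[7], "15 + 15 + 2")
  expect_identical(sim$copies$n_monomers[7], 32L)
  expect_identical(sim$copies$n_monomers[8], 92L)
  expect_identical(sim$copies$status[c(1, 7, 8, 10)],
                   c("canonical", "variant", "variant", "canonical"))
  # delete_types removes all monomers of the given types from the copy
  spec2 <- hor_array_spec(unit = 1:10, n_copies = 5, seed = 97,
                          variant_events = list(list(copy = 2, event = "delete_types",
                                                     types = c(6, 7))))
  sim2 <- build_array(spec2)
  expect_identical(sim2$copies$n_monomers, c(10L, 8L, 10L, 10L, 10L))
  expect_identical(sim2$copies$signature[2], "(5 + 3)")
  expect_error(hor_array_spec(unit = 1:10, n_copies = 5,
                              variant_events = list(list(copy = 2, event = "swap"))),
               class = "cascadeHOR_param_error")
})

test_that("realized intra-type divergence concentrates near 2m(1-m)", {
  set.seed(98)
  for (m in c(0.005, 0.01, 0.03)) {
    spec <- hor_array_spec(unit = rep(1L, 40), n_types = 1, n_copies = 1,
                           per_base_mutation = m, flank_len = 0,
                           seed = round(1000 * m))
    sim <- build_array(spec)
    seqs <- substring(unname(sim$sequence), sim$monomers$start + 1,
                      sim$monomers$end)
    d <- build_divergence_matrix(seqs)
    mean_div <- mean(d[upper.tri(d)])
    expected <- 2 * m * (1 - m)
    expect_gt(mean_div, 0.5 * expected)
    expect_lt(mean_div, 1.5 * expected)
  }
})

test_that("minus-strand arrays read in unit order on the reverse complement", {
  spec <- hor_array_spec(unit = unit17, n_copies = 3, per_base_mutation = 0,
                         strand = "-", flank_len = 100, seed = 99)
  sim <- build_array(spec)
  expect_true(all(sim$monomers$strand == "-"))
  # genome-order types are the reverse of the unit tandem
  expect_identical(sim$monomers$type, rev(rep(unit17, 3)))
  m <- scan_monomers(sim$sequence, sim$query)
  expect_equal(nrow(m), 51L)
  expect_true(all(m$strand == "-"))
})

test_that("array specs round-trip through JSON", {
  spec <- hor_array_spec(unit = unit17, n_copies = 7, seed = 100,
                         per_base_mutation = 0.02,
                         variant_events = list(list(copy = 2, event = "delete_types",
                                                    types = c(3, 4))))
  path <- tempfile(fileext = ".json")
  write_array_spec(spec, path)
  back <- read_array_spec(path)
  expect_identical(back$unit, spec$unit)
  expect_identical(back$n_copies, spec$n_copies)
  expect_identical(back$seed, spec$seed)
  expect_equal(back$variant_events[[1]]$types, c(3, 4))
  expect_identical(build_array(back)$sequence, build_array(spec)$sequence)
})

test_that("sim artifacts are written as FASTA, BED and TSV", {
  sim <- sim_cascading17(2, seed = 101)
  dir <- tempfile()
  paths <- write_sim(sim, dir)
  expect_true(all(file.exists(paths)))
  fa <- Biostrings::readDNAStringSet(paths["fasta"])
  expect_equal(unname(Biostrings::width(fa)), unname(nchar(sim$sequence)))
  bed <- read.delim(paths["bed"], header = FALSE)
  expect_equal(nrow(bed), nrow(sim$monomers))
  expect_identical(bed$V4[1], "t1")
})
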