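test_that("divergence matrix matches the DP oracle", {
  expect_identical(build_divergence_matrix("ACGTACGT"), matrix(0, 1, 1))
  expect_identical(build_divergence_matrix(c("ACGT", "ACGT")),
                   matrix(0, 2, 2))
  set.seed(51)
  seqs <- replicate(3, rand_dna(60))
  d <- build_divergence_matrix(seqs)
  expect_true(isSymmetric(d))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(d[i, j], if (i == j) 0 else div_oracle(seqs[i], seqs[j]))
  }
})

test_that("family assignment is the single-linkage transitive closure", {
  d <- matrix(c(0, 0.03, 0.08,
                0.03, 0, 0.03,
                0.08, 0.03, 0), 3, 3)
  expect_identical(assign_families(d), c(1L, 1L, 1L))
  d2 <- matrix(c(0, 0.2, 0.2,
                 0.2, 0, 0.03,
                 0.2, 0.03, 0), 3, 3)
  expect_identical(assign_families(d2), c(1L, 2L, 2L))
  expect_error(assign_families(d, threshold = 0.6),
               class = "cascadeHOR_param_error")
})

test_that("labels agree with igraph connected components on random matrices", {
  set.seed(52)
  for (rep in 1:10) {
    n <- 40
    d <- matrix(runif(n * n, 0, 0.2), n, n)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    labs <- assign_families(d, threshold = 0.05)
    g <- igraph::graph_from_adjacency_matrix(d < 0.05, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    # same partition up to renaming
    expect_identical(labs, as.integer(match(comp, unique(comp))))
  }
})

test_that("recovered family count matches ground truth in the recovery regime", {
  sim <- sim_cascading17(6, m = 0.01, seed = 53)
  m <- scan_monomers(sim$sequence, sim$query)
  labs <- assign_families(m, threshold = 0.05)
  expect_equal(length(unique(labs)), 16L)
  expect_identical(labs, as.integer(match(sim$monomers$type, unique(sim$monomers$type))))
})

test_that("threshold monotonicity: higher thresholds never increase family count", {
  set.seed(54)
  seqs <- vapply(1:30, function(i) rand_dna(80), "")
  d <- build_divergence_matrix(seqs)
  ks <- vapply(c(0.05, 0.1, 0.2, 0.3, 0.45),
               function(th) length(unique(assign_families(d, th))), numeric(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("family consensus takes majority per column with A<C<G<T ties", {
  expect_identical(unname(family_consensus(c("ACGT", "ACGT"), c(1L, 1L))), "ACGT")
  expect_identical(unname(family_consensus(c("ACGT", "ACGA", "ACGT"), rep(1L, 3))),
                   "ACGT")
  # 2-way tie in last column: A beats T
  expect_identical(unname(family_consensus(c("ACGT", "ACGA"), c(1L, 1L))), "ACGA")
})

test_that("consensus of a mutated family recovers the seed sequence", {
  set.seed(55)
  seed_seq <- rand_dna(171)
  mut <- function(s, m) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < m)
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(ch, collapse = "")
  }
  members <- vapply(1:50, function(i) mut(seed_seq, 0.02), "")
  cons <- family_consensus(members, rep(1L, 50))
  expect_lt(divergence(unname(cons), seed_seq), 0.01)
})

test_that("streaming assignment agrees with the exact matrix mode", {
  sims <- list(
    sim_cascading17(8, m = 0.01, seed = 61,
                    variant_events = list(list(copy = 4, event = "duplicate_row",
                                               row = 1, times = 2))),
    sim_willard10(10, m = 0.015, seed = 62))
  for (sim in sims) {
    m <- scan_monomers(sim$sequence, sim$query)
    exact <- assign_families(m, method = "exact")
    stream <- assign_families(m, method = "stream")
    expect_identical(exact, stream)
  }
})

test_that("hor_families bundles labels, consensi and divergences coherently", {
  sim <- sim_cascading17(4, m = 0.01, seed = 63)
  m <- scan_monomers(sim$sequence, sim$query)
  fam <- hor_families(m)
  expect_equal(fam$k, 16L)
  expect_equal(length(fam$labels), nrow(m))
  expect_equal(names(fam$consensus), paste0("t", 1:16))
  expect_true(all(fam$div_to_consensus < 0.05))
  tsv <- tempfile(fileext = ".tsv")
  fa <- tempfile(fileext = ".fa")
  write_families_tsv(fam, tsv)
  write_family_consensus_fasta(fam, fa)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), nrow(m))
  expect_equal(tab$family_label[1], "t1")
  cons <- Biostrings::readDNAStringSet(fa)
  expect_equal(names(cons), paste0("t", 1:16))
})
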