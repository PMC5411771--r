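test_that("genome simulation is deterministic with uniform composition", {
  cfg <- sim_config(genome_length = 1000, seed = 1)
  g1 <- simulate_genome(cfg)
  expect_identical(g1, simulate_genome(cfg))
  expect_equal(nchar(g1), 1000)

  big <- simulate_genome(sim_config(genome_length = 1e5, seed = 2))
  counts <- table(strsplit(big, "")[[1]])
  # binomial bound: 3 sigma around 25% each
  expect_true(all(abs(counts / 1e5 - 0.25) < 3 * sqrt(0.25 * 0.75 / 1e5)))

  rep_cfg <- sim_config(genome_length = 5000, seed = 3,
                        repeat_spec = list(unit_length = 40, copies = 2))
  gr <- simulate_genome(rep_cfg)
  unit <- substr(gr, 1, 40)
  hits <- gregexpr(unit, gr, fixed = TRUE)[[1]]
  expect_gte(length(hits), 2)
})

test_that("read simulation: count, strand, error-free substrings", {
  cfg <- sim_config(genome_length = 10000, coverage = 30, read_length = 100,
                    error_rate = 0, seed = 4)
  genome <- simulate_genome(cfg)
  reads <- simulate_reads(genome, cfg)
  expect_length(reads, 3000) # round(30 * 10000 / 100)
  expect_true(all(nchar(reads) == 100))
  # every error-free read is a substring of the genome or its rc
  both <- c(genome, revcomp(genome))
  set.seed(5)
  for (r in sample(reads, 40)) {
    expect_true(any(vapply(both, function(s) grepl(r, s, fixed = TRUE),
                           TRUE)))
  }
  # about half the reads come from the reverse strand
  fwd <- vapply(sample(reads, 200), function(r) grepl(r, genome,
                                                      fixed = TRUE), TRUE)
  expect_gt(mean(fwd), 0.35)
  expect_lt(mean(fwd), 0.65)
})

test_that("realized substitution rate matches the configured error rate", {
  cfg0 <- sim_config(genome_length = 20000, coverage = 25,
                     error_rate = 0, seed = 6)
  cfg1 <- sim_config(genome_length = 20000, coverage = 25,
                     error_rate = 0.01, seed = 6)
  genome <- simulate_genome(cfg0)
  clean <- simulate_reads(genome, cfg0)
  noisy <- simulate_reads(genome, cfg1) # same seed: same starts/strands
  mism <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, clean, noisy)
  rate <- sum(mism) / sum(nchar(clean))
  n <- sum(nchar(clean))
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / n))
})

test_that("exact assembler: linear genomes give one unitig, forks three", {
  k <- 15
  genome <- genome_unique_km1(2000, k, seed = 7)
  reads <- tiling_reads(genome)
  u <- exact_unitigs(reads, k, 1)
  expect_identical(u, canonical_sequence(genome))

  # a shared (k-1)-mer at two loci forces a fork
  g2 <- genome_unique_km1(3000, k, seed = 8)
  shared <- substr(g2, 1000, 1000 + k - 2)
  g2mod <- paste0(substr(g2, 1, 2000), shared, substr(g2, 2001, 3000))
  u2 <- exact_unitigs(tiling_reads(g2mod, 60, 10), k, 1)
  expect_gte(length(u2), 3)
})

test_that("exact k-mer counting on a tiny instance", {
  tab <- exact_kmer_counts(c("ACGTA", "ACGTA"), 4)
  expect_identical(tab$kmer, sort(canonical_sequence(c("ACGT", "CGTA"))))
  expect_equal(tab$count, c(2, 2))
})

test_that("N50 and NG50 follow the cumulative-length definitions", {
  expect_equal(n50(c(100)), 100)
  expect_equal(ng50(c(100), 100), 100)
  expect_equal(n50(c(50, 40, 30, 20, 10)), 40)
  expect_equal(ng50(c(50, 40, 30, 20, 10), 150), 40)
  expect_equal(ng50(c(50, 40, 30, 20, 10), 200), 30)
  expect_equal(n50(numeric(0)), 0)
  # assembly covering less than half the genome: NG50 undefined -> 0
  expect_equal(ng50(c(10, 10), 100), 0)
})
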