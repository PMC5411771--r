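test_that("load pass: k-mer extraction, N-splitting, exact distinct count", {
  cf <- cascading_bloom_filter(2^14, c = 2)
  lp <- load_pass("ACGTA", 4, cf)
  expect_equal(lp$kmers, 2)
  expect_equal(lp$distinct, 2) # ACGT, CGTA canonicalized

  cf2 <- cascading_bloom_filter(2^14, c = 2)
  lp2 <- load_pass("ACNGT", 3, cf2) # both segments shorter than k
  expect_equal(lp2$kmers, 0)
  expect_equal(lp2$distinct, 0)

  cf3 <- cascading_bloom_filter(2^14, c = 2)
  lp3 <- load_pass(character(0), 5, cf3)
  expect_equal(lp3$kmers, 0)
  expect_equal(lp3$distinct, 0)

  # distinct count equals the genome's canonical k-mer set on clean reads
  k <- 21
  genome <- simulate_genome(sim_config(genome_length = 3000, seed = 5))
  reads <- tiling_reads(genome)
  cf4 <- cascading_bloom_filter(2^18, c = 2)
  expect_equal(load_pass(reads, k, cf4)$distinct,
               nrow(exact_kmer_counts(genome, k)))
})

test_that("solid reads are exactly the reads made of solid k-mers", {
  k <- 21
  cfg <- sim_config(genome_length = 4000, coverage = 30, error_rate = 0,
                    seed = 6)
  genome <- simulate_genome(cfg)
  reads <- simulate_reads(genome, cfg)
  cf <- cascading_bloom_filter(size_for_fpr(5e4, 1e-9), c = 2)
  load_pass(reads, k, cf)
  g <- dbg(cf, k)
  # error-free reads from a 30x covered genome are solid at c = 2
  expect_true(all(is_solid_read(reads[1:50], g)))
  # one unique error k-mer makes a read non-solid
  bad <- reads[1]
  substr(bad, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                 substr(bad, 50, 50))[1]
  expect_false(is_solid_read(bad, g))
  # reads shorter than k are never solid
  expect_false(is_solid_read(substr(reads[1], 1, k - 1), g))
})

test_that("branch-free reads stay whole; reads crossing a fork are split", {
  k <- 9
  trunk <- genome_unique_km1(200, k, seed = 31)
  g <- dbg(exactish_filter(trunk, k), k)
  read <- substr(trunk, 50, 149)
  seg <- split_at_branches(read, g)
  expect_equal(nrow(seg), 1)
  expect_identical(seg$sequence, read)
  expect_equal(seg$start, 1)
  expect_equal(seg$end, 100)
  # a read of exactly k bases is a single one-k-mer segment
  seg1 <- split_at_branches(substr(trunk, 50, 50 + k - 1), g)
  expect_equal(nrow(seg1), 1)

  # construct a genuine fork: two long branches sharing the trunk prefix
  mid <- 100
  x <- substr(trunk, mid, mid + k - 1)
  true_next <- substr(trunk, mid + k, mid + k)
  alt <- setdiff(c("A", "C", "G", "T"), true_next)[1]
  branch <- paste0(substr(trunk, mid + 1, mid + k - 1), alt,
                   substr(genome_unique_km1(80, k, seed = 33), 1, 3 * k))
  g2 <- dbg(exactish_filter(c(trunk, branch), k), k)
  read2 <- substr(trunk, mid - 20, mid + 20)
  seg2 <- split_at_branches(read2, g2)
  expect_equal(nrow(seg2), 2)
  # segments meet at the branch k-mer and reconstitute the read
  expect_identical(substr(seg2$sequence[1],
                          nchar(seg2$sequence[1]) - k + 1,
                          nchar(seg2$sequence[1])), x)
  expect_identical(paste0(seg2$sequence[1],
                          substr(seg2$sequence[2], k, nchar(seg2$sequence[2]))),
                   read2)
})

test_that("seed extension recovers a linear genome and deduplicates", {
  k <- 15
  genome <- genome_unique_km1(500, k, seed = 41)
  g <- dbg(exactish_filter(genome, k), k)
  tracking <- bloom_filter(size_for_fpr(600, 1e-9), h = 4)
  seed_seq <- substr(genome, 240, 260)
  res <- extend_seed(seed_seq, g, tracking)
  expect_false(res$skipped)
  expect_identical(res$sequence, genome)
  # a second seed from the same region is skipped
  res2 <- extend_seed(substr(genome, 100, 130), g, tracking)
  expect_true(res2$skipped)
})

test_that("injected false-positive spurs do not change the unitig
           (look-ahead robustness)", {
  k <- 15
  genome <- genome_unique_km1(400, k, seed = 51)
  seed_seq <- substr(genome, 190, 215)

  base <- exactish_filter(genome, k)
  plain <- extend_seed(seed_seq, dbg(base, k),
                       bloom_filter(2^13, h = 4))

  # same filter plus spur k-mers branching off the path, spur <= k nodes
  spurred <- exactish_filter(genome, k)
  at <- 200
  alt <- setdiff(c("A", "C", "G", "T"), substr(genome, at + k, at + k))[1]
  spur <- paste0(substr(genome, at + 1, at + k - 1), alt,
                 random_dna(k - 1)) # k spur nodes, at the pruning bound
  bf_insert_kmers(spurred, spur, k)
  with_spur <- extend_seed(seed_seq, dbg(spurred, k),
                           bloom_filter(2^13, h = 4))
  expect_identical(with_spur$sequence, plain$sequence)
})

test_that("assembly of tiling error-free reads reconstructs the genome", {
  k <- 21
  genome <- genome_unique_km1(5000, k, seed = 61)
  reads <- tiling_reads(genome)
  asm <- assemble(reads, k, min_count = 1, target_fpr = 1e-6,
                  genome_size = nchar(genome))
  expect_equal(asm$report$n_unitigs, 1)
  expect_identical(canonical_sequence(unname(asm$unitigs[1])),
                   canonical_sequence(genome))
  expect_equal(asm$report$n50, nchar(genome))
  expect_equal(asm$report$ng50, nchar(genome))
  expect_equal(asm$report$percent_solid, 100)
})

test_that("assembling an empty read set yields an empty report", {
  asm <- assemble(character(0), 21, min_count = 2, bits_per_level = 1024)
  expect_equal(asm$report$n_unitigs, 0)
  expect_equal(asm$report$total_bases, 0)
  expect_equal(asm$report$n50, 0)
  expect_length(asm$unitigs, 0)
})

test_that("assembly is deterministic", {
  cfg <- sim_config(genome_length = 3000, coverage = 40,
                    error_rate = 0.005, seed = 71)
  reads <- simulate_reads(simulate_genome(cfg), cfg)
  a1 <- assemble(reads, 21, min_count = 2, target_fpr = 0.01)
  a2 <- assemble(reads, 21, min_count = 2, target_fpr = 0.01)
  expect_identical(a1$unitigs, a2$unitigs)
  expect_identical(a1$report, a2$report)
})

test_that("assembly agrees with the exact oracle across a repeat fork", {
  k <- 15
  cfg <- sim_config(genome_length = 6000, coverage = 40, error_rate = 0,
                    seed = 81,
                    repeat_spec = list(unit_length = 3 * k, copies = 2))
  genome <- simulate_genome(cfg)
  reads <- simulate_reads(genome, cfg)
  asm <- assemble(reads, k, min_count = 1, target_fpr = 1e-6)
  expect_identical(sort(canonical_sequence(unname(asm$unitigs))),
                   exact_unitigs(reads, k, 1))
})

test_that("the solid-read percentage is reported to one decimal", {
  expect_equal(solid_read_stats(9, 12)$percent, 75)
  expect_equal(solid_read_stats(1, 3)$percent, 33.3)
  expect_true(is.na(solid_read_stats(0, 0)$percent))
})
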