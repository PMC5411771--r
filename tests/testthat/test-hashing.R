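test_that("hash values are frozen (golden values) and deterministic", {
  h <- hash_kmer(c("ACGT", "TGCA", "AAAC", "GTTT"))
  # frozen by the committed per-base seed constants
  expect_identical(h$fwd[1], "f14d5bc840b6e665")
  expect_identical(h$fwd[2], "47a0ce00c9280c70")
  expect_identical(h$canonical[3], "23964e387540f786")
  # "ACGT" is its own reverse complement: fwd == rc is forced
  expect_identical(h$fwd[1], h$rc[1])
  # distinct k-mers hash differently
  expect_false(h$fwd[1] == h$fwd[2])
  # repeated calls are bit-identical
  expect_identical(hash_kmer("ACGT"), hash_kmer("ACGT"))
  # case-insensitive
  expect_identical(hash_kmer("acgt")$fwd, h$fwd[1])
})

test_that("rolling hashes equal from-scratch hashes at every window", {
  set.seed(42)
  for (k in c(15, 21, 31)) {
    seq <- random_dna(3000)
    tab <- hash_kmers(seq, k)
    expect_equal(nrow(tab), 3000 - k + 1)
    direct <- hash_kmer(substring(seq, tab$pos, tab$pos + k - 1))
    expect_identical(tab$fwd, direct$fwd)
    expect_identical(tab$rc, direct$rc)
    expect_identical(tab$canonical, direct$canonical)
  }
  # a segment of length exactly k admits zero rolls
  expect_equal(nrow(hash_kmers(random_dna(21), 21)), 1)
})

test_that("canonical hash is strand-symmetric", {
  expect_identical(hash_kmer("AAAC")$canonical, hash_kmer("GTTT")$canonical)
  set.seed(7)
  kmers <- vapply(rep(21, 500), random_dna, "")
  expect_identical(hash_kmer(kmers)$canonical,
                   hash_kmer(revcomp(kmers))$canonical)
})

test_that("windows containing non-ACGT characters are skipped, and
           whole-k-mer hashing rejects them with the position", {
  tab <- hash_kmers("ACGNACGT", 3)
  expect_identical(tab$pos, c(1L, 5L, 6L))
  err <- tryCatch(hash_kmer("ACNT"), error = function(e) e)
  expect_match(conditionMessage(err), "position 3")
})

test_that("multi-hash schedule: identity at h = 1, deterministic,
           uniform per-bit occupancy", {
  base <- hash_kmer("ACGTACGTACGTACG")$canonical
  expect_identical(as.character(multi_hash(base, h = 1)), base)
  m4 <- multi_hash(base, h = 4, seed = 3)
  expect_identical(m4, multi_hash(base, h = 4, seed = 3))
  expect_identical(m4[1, 1], base) # value_0 == base
  expect_false(any(duplicated(m4[1, ])))
  # different seeds give different schedules beyond value_0
  expect_false(all(m4 == multi_hash(base, h = 4, seed = 4)))
  expect_error(multi_hash(base, h = 0), "h")

  # per-bit occupancy of each derived stream over 1e6 random bases
  set.seed(11)
  counts <- bloomdbg:::cpp_multi_hash_bit_counts(1e6, 4L, 0)
  expect_true(all(abs(counts / 1e6 - 0.5) < 0.01))
})

test_that("single-base substitutions flip many output bits (avalanche)", {
  set.seed(5)
  expect_gte(bloomdbg:::cpp_avalanche(400L, 21L), 20)
})
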