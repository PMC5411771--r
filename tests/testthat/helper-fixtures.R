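# Fixture builders shared across test files.  Everything is generated in
# code; no data files.

# n random 16-digit hex keys (uniform over 64 bits)
random_keys <- function(n) {
  sprintf(
    "%04x%04x%04x%04x",
    sample.int(65536L, n, replace = TRUE) - 1L,
    sample.int(65536L, n, replace = TRUE) - 1L,
    sample.int(65536L, n, replace = TRUE) - 1L,
    sample.int(65536L, n, replace = TRUE) - 1L
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# error-free reads tiling the genome (every position covered, both ends
# included)
tiling_reads <- function(genome, read_length = 100, step = 25) {
  G <- nchar(genome)
  starts <- unique(c(seq(1, G - read_length + 1, by = step),
                     G - read_length + 1))
  substring(genome, starts, starts + read_length - 1)
}

# does the genome have unique (k-1)-mers (counting a k-mer and its
# reverse complement as one)?
has_unique_km1 <- function(genome, k) {
  all(exact_kmer_counts(genome, k - 1)$count == 1)
}

# deterministic genome with unique (k-1)-mers: bump the seed until the
# uniqueness condition holds
genome_unique_km1 <- function(length, k, seed = 1) {
  for (s in seed + 0:49) {
    g <- simulate_genome(sim_config(genome_length = length, seed = s))
    if (has_unique_km1(g, k)) return(g)
  }
  stop("no genome with unique (k-1)-mers found")
}

# Bloom filter loaded with exactly the k-mers of `seqs`, sized so the
# false-positive rate is negligible
exactish_filter <- function(seqs, k, h = 4, seed = 0) {
  n <- sum(pmax(nchar(seqs) - k + 1, 0))
  f <- bloom_filter(size_for_fpr(max(n, 1), 1e-9, h), h = h, seed = seed)
  bf_insert_kmers(f, seqs, k)
  f
}
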