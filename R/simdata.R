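#' Configuration for the synthetic data generator
#'
#' The defaults emulate a typical short-read whole-genome experiment for
#' this kind of assembly: 100 bp reads at 75-fold coverage with
#' substitution errors at 0.5% per base.  Reads are single-ended — the
#' unitig stage uses no pairing information.
#'
#' @param genome_length Genome length in bases.
#' @param read_length Read length in bases (default 100).
#' @param coverage Fold coverage (default 75).
#' @param error_rate Per-base substitution probability (default 0.005);
#'   indels are not simulated.
#' @param seed RNG seed for genome and read generation.
#' @param repeat_spec Optional `list(unit_length =, copies =)`: a
#'   repeat unit copied to several loci so the genome contains true
#'   branches.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 10000, coverage = 30, seed = 1)
sim_config <- function(genome_length, read_length = 100, coverage = 75,
                       error_rate = 0.005, seed = 1, repeat_spec = NULL) {
  check_number(genome_length, "genome_length", min = 1)
  check_number(read_length, "read_length", min = 1)
  check_number(coverage, "coverage", min = 1e-9)
  check_number(error_rate, "error_rate", min = 0, max = 1 - 1e-12)
  check_number(seed, "seed", min = 0)
  if (!is.null(repeat_spec)) {
    stopifnot(is.list(repeat_spec),
              all(c("unit_length", "copies") %in% names(repeat_spec)))
  }
  structure(
    list(genome_length = genome_length, read_length = read_length,
         coverage = coverage, error_rate = error_rate, seed = seed,
         repeat_spec = repeat_spec),
    class = "sim_config"
  )
}

#' Simulate a random genome
#'
#' Uniform random sequence over A/C/G/T.  If `repeat_spec` is set, the
#' leading `unit_length` bases are copied to `copies - 1` additional
#' random loci, creating exact repeats (and hence true branch points in
#' the de Bruijn graph).  Deterministic given the config seed.
#'
#' @param cfg A [sim_config()].
#' @return A single DNA string.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    g <- paste(sample(c("A", "C", "G", "T"), cfg$genome_length,
                      replace = TRUE), collapse = "")
    if (!is.null(cfg$repeat_spec)) {
      L <- cfg$repeat_spec$unit_length
      copies <- cfg$repeat_spec$copies
      stopifnot(L >= 1, L <= cfg$genome_length, copies >= 2)
      unit <- substr(g, 1, L)
      for (i in seq_len(copies - 1)) {
        at <- sample.int(cfg$genome_length - L + 1, 1)
        substr(g, at, at + L - 1) <- unit
      }
    }
    g
  })
}

#' Simulate error-bearing single-end reads
#'
#' Draws `round(coverage * genome_length / read_length)` reads with
#' uniform start positions, each taken from the forward or reverse strand
#' with probability 1/2, then applies i.i.d. substitution errors at
#' `error_rate`.  Deterministic given the config seed.
#'
#' @param genome A DNA string (see [simulate_genome()]).
#' @param cfg A [sim_config()].
#' @return A named character vector of reads.
#' @export
simulate_reads <- function(genome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genome <- as.character(genome)[1]
  G <- nchar(genome)
  L <- cfg$read_length
  if (L > G) {
    stop_bloomdbg("read_length exceeds genome_length",
                  "bloomdbg_parameter_error")
  }
  withr::with_seed(cfg$seed + 1, {
    n <- round(cfg$coverage * G / L)
    starts <- sample.int(G - L + 1, n, replace = TRUE)
    reads <- substring(genome, starts, starts + L - 1)
    rc <- runif(n) < 0.5
    if (any(rc)) {
      reads[rc] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads[rc])
      ))
    }
    if (cfg$error_rate > 0) {
      reads <- as.character(cpp_add_substitutions(reads,
                                                  cfg$error_rate)$reads)
    }
    names(reads) <- sprintf("read_%d", seq_len(n))
    reads
  })
}

#' Exact reference assembly (verification oracle)
#'
#' A deliberately brute-force reimplementation of the unitig algorithm
#' over exact data structures: k-mers are counted in a hash table, the
#' solid set is the k-mers with count `>= min_count`, branch survival is
#' decided by a breadth-first bounded search on string sets, and
#' deduplication uses an exact visited set instead of a tracking Bloom
#' filter.  With the probabilistic assembler's false-positive rate driven
#' to ~0, [assemble()] must produce exactly this set of canonical unitig
#' sequences.
#'
#' @param reads Character vector of reads (or `XStringSet` / file paths).
#' @param k K-mer length.
#' @param min_count Minimum k-mer occurrence threshold.
#' @param lookahead Look-ahead depth in nodes (default `k`).
#' @param min_unitig_len Minimum unitig length (default `k`).
#' @return Sorted character vector of canonical unitig sequences.
#' @export
exact_unitigs <- function(reads, k, min_count, lookahead = NULL,
                          min_unitig_len = NULL) {
  check_number(k, "k", min = 3)
  check_number(min_count, "min_count", min = 1)
  lookahead <- lookahead %||% k
  min_unitig_len <- min_unitig_len %||% k
  reads <- as_read_vector(reads)
  cpp_exact_unitigs(reads, as.integer(k), as.integer(min_count),
                    as.integer(lookahead), as.integer(min_unitig_len))
}

#' Exact canonical k-mer occurrence counts
#'
#' Hash-table counting of canonical k-mers, for verification at small
#' scale.
#'
#' @inheritParams exact_unitigs
#' @return A data.frame with columns `kmer` (canonical) and `count`.
#' @export
exact_kmer_counts <- function(reads, k) {
  check_number(k, "k", min = 1)
  reads <- as_read_vector(reads)
  res <- cpp_exact_kmer_counts(reads, as.integer(k))
  data.frame(kmer = res$kmer, count = res$count, stringsAsFactors = FALSE)
}
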