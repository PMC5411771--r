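#' First pass: load k-mers into a cascading Bloom filter
#'
#' Extracts every k-mer of every ACGT segment of the reads (reads are
#' split at non-ACGT characters), canonicalizes it, and inserts it into
#' the cascade once per occurrence.  Optionally counts the distinct
#' canonical k-mers exactly (2-bit packed set for `k <= 32`).
#'
#' @param reads Character vector of read sequences, an `XStringSet`, or
#'   FASTA/FASTQ file path(s).
#' @param k K-mer length.
#' @param cascade A [cascading_bloom_filter()] to load into.
#' @param count_distinct Count distinct canonical k-mers during the pass?
#' @return A list with `cascade` (the loaded filter), `kmers` (k-mer
#'   occurrences inserted) and `distinct` (exact distinct canonical
#'   k-mer count, or `NA` if not requested).
#' @export
load_pass <- function(reads, k, cascade, count_distinct = TRUE) {
  stopifnot(inherits(cascade, "cascading_bloom_filter"))
  check_number(k, "k", min = 3)
  reads <- as_read_vector(reads)
  res <- cpp_load_pass(cascade$ptr, reads, as.integer(k), count_distinct)
  list(cascade = cascade, kmers = res$kmers, distinct = res$distinct)
}

#' Identify solid reads
#'
#' A read is solid when it has at least one k-mer and every k-mer of
#' every ACGT segment is present in the solid filter — i.e. it consists
#' entirely of k-mers meeting the occurrence threshold, and so is likely
#' to spell a correct path in the de Bruijn graph.
#'
#' @param reads Character vector of reads (or `XStringSet` / file paths).
#' @param graph A [dbg()] graph over the solid filter.
#' @return Logical vector, one element per read.
#' @export
is_solid_read <- function(reads, graph) {
  stopifnot(inherits(graph, "prob_dbg"))
  reads <- as_read_vector(reads)
  cpp_is_solid_read(graph$filter$ptr, is_cascade(graph), reads, graph$k)
}

#' Split a solid read at branch points
#'
#' Returns the maximal sub-segments of the read whose interior k-mer
#' steps are unitig-interior edges: each consecutive k-mer pair (x, y)
#' must have y as the unique surviving successor of x and x as the unique
#' surviving predecessor of y (after look-ahead pruning).  Solid reads
#' spanning branch points must be split so each piece can seed its own
#' unitig; concatenating the segments with (k-1)-base overlaps
#' reconstitutes the read's k-mer walk.
#'
#' @param read A single read sequence.
#' @param graph A [dbg()] graph over the solid filter.
#' @return A data.frame with columns `start`, `end` (1-based base
#'   coordinates in the read) and `sequence`.
#' @export
split_at_branches <- function(read, graph) {
  stopifnot(inherits(graph, "prob_dbg"))
  read <- as.character(read)[1]
  res <- cpp_split_at_branches(graph$filter$ptr, is_cascade(graph), read,
                               graph$k, graph$lookahead)
  data.frame(start = res$start, end = res$end, sequence = res$sequence,
             stringsAsFactors = FALSE)
}

#' Extend a seed segment into a unitig
#'
#' If every k-mer of the segment is already present in the tracking
#' filter the seed is skipped (it lies in a neighbourhood that has
#' already been assembled).  Otherwise the segment is extended to the
#' right from its last k-mer and to the left from its first (by walking
#' the reverse complement), one base per step.  A step is taken only when
#' the next k-mer is the unique surviving extension and the current k-mer
#' is its unique surviving extension in the reverse direction; extension
#' halts at dead ends and true branches.  All k-mers of the resulting
#' unitig are inserted into the tracking filter.
#'
#' @param segment A seed segment (every k-mer solid, branch-free).
#' @param graph A [dbg()] graph over the solid filter.
#' @param tracking A [bloom_filter()] recording k-mers already assembled.
#' @param min_unitig_len Minimum length for the unitig to be emitted
#'   (default `k`).
#' @return A list with `skipped` (logical), `sequence` (the unitig, empty
#'   if skipped), `emitted` (length >= `min_unitig_len`?) and `steps`
#'   (membership probes spent).
#' @export
extend_seed <- function(segment, graph, tracking, min_unitig_len = NULL) {
  stopifnot(inherits(graph, "prob_dbg"), inherits(tracking, "bloom_filter"))
  min_unitig_len <- min_unitig_len %||% graph$k
  res <- cpp_extend_seed(graph$filter$ptr, is_cascade(graph), tracking$ptr,
                         toupper(as.character(segment)[1]),
                         graph$lookahead, as.integer(min_unitig_len),
                         graph$k)
  list(skipped = res$skipped, sequence = res$sequence, emitted = res$emit,
       steps = res$steps)
}

#' Assemble unitigs from reads with a Bloom filter de Bruijn graph
#'
#' The two-pass pipeline: (1) load all k-mers into a cascading Bloom
#' filter of `min_count` levels, whose last level is the solid-k-mer set;
#' (2) iterate the reads in input order, keep the solid reads, split them
#' at branch points, and extend each piece left and right through the
#' graph with look-ahead pruning of short false branches, deduplicating
#' via a tracking Bloom filter.
#'
#' Per-level filter size is taken from `bits_per_level` if given;
#' otherwise it is computed with [size_for_fpr()] from a presampling
#' pass that counts distinct canonical k-mers exactly, targeting
#' `target_fpr` (default 5%, a good operating point for both memory and
#' run time).
#'
#' @param reads Character vector of reads, an `XStringSet`, or FASTA /
#'   FASTQ file path(s) (gzip accepted).
#' @param k K-mer length (odd values recommended).
#' @param min_count Minimum k-mer occurrence threshold `c`; also the
#'   number of cascade levels (typically 2-4).
#' @param bits_per_level Bits per cascade level (rounded up to a byte).
#' @param target_fpr Target false-positive rate used to size the filters
#'   when `bits_per_level` is absent.
#' @param h Number of hash functions per filter.
#' @param lookahead Look-ahead depth in nodes (default `k`).
#' @param min_unitig_len Minimum unitig length to report (default `k`).
#' @param seed Hash seed.
#' @param genome_size Optional genome size in bases for NG50 reporting.
#' @return An object of class `unitig_assembly`: a list with `unitigs`
#'   (named character vector), `seed_read` (index of the seeding read),
#'   `lengths`, `report` (run metrics, see Details) and `params`.
#'
#' @details The `report` contains the distinct k-mer count, solid-read
#' counts and percentage, per-level insert counts, the realized
#' false-positive rate of the solid (last-level) filter and of level 1
#' (both via [fpr_analytic()] with the exact per-level insert counts),
#' peak allocated filter bits, traversal step count, unitig count, total
#' bases, N50 and (when `genome_size` is given) NG50.
#'
#' @seealso [exact_unitigs()] for the exact reference implementation,
#'   [write_unitigs()] to export FASTA.
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 2000, coverage = 20,
#'                   error_rate = 0, seed = 7)
#' genome <- simulate_genome(cfg)
#' reads <- simulate_reads(genome, cfg)
#' asm <- assemble(reads, k = 21, min_count = 1, target_fpr = 0.001)
#' summary(asm)
assemble <- function(reads, k, min_count = 2, bits_per_level = NULL,
                     target_fpr = NULL, h = 4, lookahead = NULL,
                     min_unitig_len = NULL, seed = 0, genome_size = NULL) {
  check_number(k, "k", min = 3)
  check_number(min_count, "min_count", min = 1)
  lookahead <- lookahead %||% k
  min_unitig_len <- min_unitig_len %||% k
  check_number(lookahead, "lookahead", min = 1)
  reads <- as_read_vector(reads)

  distinct <- NA_real_
  if (is.null(bits_per_level)) {
    target_fpr <- target_fpr %||% 0.05
    distinct <- cpp_distinct_kmers(reads, as.integer(k))
    bits_per_level <- size_for_fpr(max(distinct, 1), target_fpr, h)
  }

  cascade <- cascading_bloom_filter(bits_per_level, c = min_count, h = h,
                                    seed = seed)
  lp <- load_pass(reads, k, cascade, count_distinct = is.na(distinct))
  if (is.na(distinct)) distinct <- lp$distinct
  info <- cbf_info(cascade)
  tracking <- bloom_filter(info$m, h = h, seed = seed)
  bits_allocated <- sum(info$level_bits) + bf_bits(tracking)
  cbf_drop_early(cascade)

  res <- cpp_pass2(cascade$ptr, TRUE, tracking$ptr, reads, as.integer(k),
                   as.integer(lookahead), as.integer(min_unitig_len))

  unitigs <- as.character(res$unitigs)
  names(unitigs) <- if (length(unitigs)) {
    sprintf("unitig_%d", seq_along(unitigs))
  } else {
    character(0)
  }
  lens <- nchar(unitigs)

  stats <- solid_read_stats(res$n_solid_reads, res$n_reads)
  report <- list(
    k = k, min_count = min_count, h = h, lookahead = lookahead,
    min_unitig_len = min_unitig_len,
    bits_per_level = info$m, levels = info$c,
    bits_allocated = bits_allocated,
    level_inserts = info$level_inserts,
    distinct_kmers = distinct,
    kmer_occurrences = lp$kmers,
    fpr = fpr_analytic(info$m, h, info$level_inserts[info$c]),
    fpr_level1 = fpr_analytic(info$m, h, info$level_inserts[1]),
    n_reads = res$n_reads,
    n_reads_with_kmer = res$n_reads_with_kmer,
    n_solid_reads = res$n_solid_reads,
    percent_solid = stats$percent,
    n_unitigs = length(unitigs),
    total_bases = sum(lens),
    n50 = n50(lens),
    ng50 = if (is.null(genome_size)) NA_real_ else ng50(lens, genome_size),
    genome_size = genome_size %||% NA_real_,
    steps = res$steps
  )

  structure(
    list(
      unitigs = unitigs, seed_read = as.integer(res$seed_read),
      lengths = lens, report = report,
      params = list(k = k, min_count = min_count, h = h,
                    bits_per_level = info$m, lookahead = lookahead,
                    min_unitig_len = min_unitig_len, seed = seed),
      solid_filter = cascade, tracking = tracking
    ),
    class = "unitig_assembly"
  )
}

#' Solid-read report arithmetic
#'
#' The percentage of solid reads implied by a solid and a total read
#' count, as printed in assembly reports (one decimal place).
#'
#' @param n_solid Number of solid reads.
#' @param n_total Total number of reads.
#' @return A list with `n_solid`, `n_total` and `percent` (rounded to one
#'   decimal).
#' @export
#' @examples
#' solid_read_stats(782886725, 868593056)$percent
solid_read_stats <- function(n_solid, n_total) {
  check_number(n_solid, "n_solid", min = 0)
  check_number(n_total, "n_total", min = 0)
  pct <- if (n_total > 0) round(100 * n_solid / n_total, 1) else NA_real_
  list(n_solid = n_solid, n_total = n_total, percent = pct)
}

#' @export
print.unitig_assembly <- function(x, ...) {
  r <- x$report
  cat(sprintf("Unitig assembly: k = %d, c = %d, h = %d\n",
              r$k, r$min_count, r$h))
  cat(sprintf("  %d unitigs, %.0f bases, N50 = %.0f\n",
              r$n_unitigs, r$total_bases, r$n50))
  if (!is.na(r$ng50)) {
    cat(sprintf("  NG50 = %.0f (genome size %.0f)\n", r$ng50, r$genome_size))
  }
  cat(sprintf("  solid reads: %.0f / %.0f (%.1f%%)\n",
              r$n_solid_reads, r$n_reads, r$percent_solid))
  cat(sprintf("  solid-filter FPR: %.3g (level 1: %.3g)\n",
              r$fpr, r$fpr_level1))
  invisible(x)
}

#' @export
summary.unitig_assembly <- function(object, ...) {
  r <- object$report
  print(object)
  cat(sprintf("  distinct k-mers: %.0f (occurrences: %.0f)\n",
              r$distinct_kmers, r$kmer_occurrences))
  cat(sprintf("  filter: %d levels x %.0f bits + tracking = %.0f bits\n",
              r$levels, r$bits_per_level, r$bits_allocated))
  cat(sprintf("  traversal probes: %.0f\n", r$steps))
  invisible(r)
}

#' Unitig sequences of an assembly
#'
#' @param x A `unitig_assembly`.
#' @return Named character vector of unitig sequences.
#' @export
unitigs <- function(x) {
  stopifnot(inherits(x, "unitig_assembly"))
  x$unitigs
}
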