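#' Assembly contiguity metrics
#'
#' `n50()` is the largest length L such that sequences of length >= L sum
#' to at least half the total assembly length.  `ng50()` replaces half
#' the assembly length with half the genome size; if the assembly covers
#' less than half the genome, NG50 is undefined and 0 is returned.
#'
#' @param lengths Non-negative sequence lengths.
#' @param genome_size Genome size in bases (for `ng50()`).
#' @return A single length (0 for an empty assembly).
#' @export
#' @examples
#' n50(c(50, 40, 30, 20, 10))           # 40
#' ng50(c(50, 40, 30, 20, 10), 150)     # 40
n50 <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0 || sum(lengths) == 0) {
    return(0)
  }
  half_at(lengths, sum(lengths) / 2)
}

#' @rdname n50
#' @export
ng50 <- function(lengths, genome_size) {
  check_number(genome_size, "genome_size", min = 1)
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0 || sum(lengths) < genome_size / 2) {
    return(0)
  }
  half_at(lengths, genome_size / 2)
}

half_at <- function(lengths, half) {
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= half)[1]]
}

#' Sweep assembly quality against Bloom filter false-positive rate
#'
#' Re-assembles the same read set at several filter sizes chosen so that
#' the realized false-positive rate of the solid (last-level) filter hits
#' the requested targets, and reports contiguity and traversal effort at
#' each point.  Because the mapping from per-level bits to the solid
#' filter's realized FPR depends on how heavily the earlier cascade
#' levels are loaded, the sweep first measures a bits-to-FPR curve with
#' cheap load-only passes and inverts it.
#'
#' @param reads Character vector of reads (or `XStringSet` / file paths).
#' @param k K-mer length.
#' @param min_count Minimum k-mer occurrence threshold (cascade levels).
#' @param targets Realized solid-filter FPRs to aim for.
#' @param h Hash functions per filter.
#' @param seed Hash seed.
#' @param genome_size Genome size for NG50.
#' @param lookahead Look-ahead depth (default `k`).
#' @param grid Per-level sizes, as multiples of the distinct k-mer
#'   count, at which the bits-to-FPR curve is measured.
#' @param baseline_ratio Per-level size multiple used for the near-zero
#'   FPR baseline point.
#' @return A data.frame with one row per sweep point (baseline first):
#'   `target`, `bits_per_level`, `fpr` (realized, solid filter),
#'   `fpr_level1`, `n_unitigs`, `total_bases`, `n50`, `ng50`, `steps`.
#' @export
fpr_sweep <- function(reads, k, min_count = 3,
                      targets = c(0.02, 0.10, 0.20), h = 4, seed = 0,
                      genome_size = NULL, lookahead = NULL,
                      grid = c(0.8, 0.9, 1.0, 1.1, 1.25, 1.45, 1.9, 2.6,
                               4.5),
                      baseline_ratio = 8) {
  reads <- as_read_vector(reads)
  n_t <- cpp_distinct_kmers(reads, as.integer(k))
  measure <- function(m_bits) {
    cf <- cascading_bloom_filter(m_bits, c = min_count, h = h, seed = seed)
    load_pass(reads, k, cf, count_distinct = FALSE)
    info <- cbf_info(cf)
    fpr_analytic(info$m, h, info$level_inserts[info$c])
  }
  round_bytes <- function(bits) ceiling(bits / 8) * 8
  ms <- round_bytes(grid * n_t)
  curve <- vapply(ms, measure, numeric(1))
  ## realized FPR decreases in m; invert by interpolating log(m) on
  ## log(fpr)
  ok <- curve > 0 & curve < 1
  ord <- order(curve[ok])
  inv <- function(target) {
    exp(approx(log(curve[ok][ord]), log(ms[ok][ord]), xout = log(target),
               rule = 2)$y)
  }
  point_m <- c(round_bytes(baseline_ratio * n_t),
               vapply(targets, function(t) round_bytes(inv(t)), numeric(1)))
  point_target <- c(NA_real_, targets)
  rows <- lapply(seq_along(point_m), function(i) {
    asm <- assemble(reads, k, min_count = min_count,
                    bits_per_level = point_m[i], h = h,
                    lookahead = lookahead, seed = seed,
                    genome_size = genome_size)
    r <- asm$report
    data.frame(target = point_target[i], bits_per_level = r$bits_per_level,
               fpr = r$fpr, fpr_level1 = r$fpr_level1,
               n_unitigs = r$n_unitigs, total_bases = r$total_bases,
               n50 = r$n50, ng50 = r$ng50, steps = r$steps)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "distinct_kmers") <- n_t
  attr(out, "curve") <- data.frame(bits_per_level = ms, fpr = curve)
  out
}
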