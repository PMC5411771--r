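#' Probabilistic de Bruijn graph over a solid-k-mer filter
#'
#' The graph is implicit: nodes are the k-mers whose canonical hash is in
#' the backing filter, and edges are discovered at query time by testing
#' the four single-base extensions of a k-mer.  The backing filter is
#' either a plain [bloom_filter()] or a [cascading_bloom_filter()] (whose
#' last level — the solid set — is queried).
#'
#' @param filter A [bloom_filter()] or [cascading_bloom_filter()]
#'   containing canonical k-mer hashes.
#' @param k K-mer length.
#' @param lookahead Look-ahead depth in nodes used to classify branches
#'   (default `k`).
#' @return An object of class `prob_dbg`.
#' @export
#' @examples
#' f <- bloom_filter(2048, h = 2)
#' bf_insert_kmers(f, "ACGTT", k = 3)
#' g <- dbg(f, k = 3)
#' dbg_successors(g, "ACG")
dbg <- function(filter, k, lookahead = NULL) {
  if (!inherits(filter, "bloom_filter") &&
      !inherits(filter, "cascading_bloom_filter")) {
    stop_bloomdbg("filter must be a bloom_filter or cascading_bloom_filter",
                  "bloomdbg_parameter_error")
  }
  check_number(k, "k", min = 3)
  lookahead <- lookahead %||% k
  check_number(lookahead, "lookahead", min = 1)
  structure(
    list(filter = filter, k = as.integer(k),
         lookahead = as.integer(lookahead)),
    class = "prob_dbg"
  )
}

is_cascade <- function(g) inherits(g$filter, "cascading_bloom_filter")

check_kmer <- function(g, kmer) {
  kmer <- toupper(as.character(kmer)[1])
  if (nchar(kmer) != g$k) {
    stop_bloomdbg(sprintf("k-mer must have length k = %d", g$k),
                  "bloomdbg_parameter_error")
  }
  kmer
}

#' Successor and predecessor bases of a k-mer
#'
#' `dbg_successors()` returns each base `b` such that the canonical form
#' of the k-mer shifted left by one with `b` appended is present in the
#' solid filter.  `dbg_predecessors()` is the strand-symmetric query: it
#' returns the bases that can precede the k-mer, obtained by querying the
#' successors of the reverse complement.
#'
#' @param g A [dbg()] graph.
#' @param kmer A k-mer string of length `g$k` (as traversed; any case).
#' @return A character vector of extension bases (subset of A/C/G/T),
#'   with the corresponding neighbour k-mers as names.
#' @export
dbg_successors <- function(g, kmer) {
  stopifnot(inherits(g, "prob_dbg"))
  kmer <- check_kmer(g, kmer)
  res <- cpp_successors(g$filter$ptr, is_cascade(g), kmer)
  stats::setNames(as.character(res$base), as.character(res$kmer))
}

#' @rdname dbg_successors
#' @export
dbg_predecessors <- function(g, kmer) {
  stopifnot(inherits(g, "prob_dbg"))
  kmer <- check_kmer(g, kmer)
  res <- cpp_successors(g$filter$ptr, is_cascade(g), revcomp(kmer))
  bases <- revcomp(as.character(res$base))
  stats::setNames(bases, revcomp(as.character(res$kmer)))
}

#' Look-ahead classification of a branch point
#'
#' For each solid single-base extension of `kmer`, a depth-bounded search
#' decides whether a walk of more than `depth` nodes hangs below it.  An
#' extension whose subtree dies out within `depth` nodes is a false
#' branch (a tip caused by a Bloom filter false positive or a recurrent
#' sequencing error) and is ignored.  The look-ahead is only invoked at
#' branching points: with zero or one solid extension the raw result is
#' returned unchanged.
#'
#' @param g A [dbg()] graph.
#' @param kmer The k-mer at the potential branch point.
#' @param depth Look-ahead depth in nodes (default `g$lookahead`).
#' @return A list with elements `kind` (one of `"dead_end"`, `"unique"`,
#'   `"false_branch_pruned"`, `"true_branch"`), `surviving` (character
#'   vector of surviving extension bases) and `n_raw` (number of solid
#'   extensions before pruning).  `kind == "unique"` implies exactly one
#'   surviving extension; `"true_branch"` implies at least two surviving
#'   extensions longer than the look-ahead depth, at which point unitig
#'   extension halts.
#' @export
lookahead_classify <- function(g, kmer, depth = NULL) {
  stopifnot(inherits(g, "prob_dbg"))
  kmer <- check_kmer(g, kmer)
  depth <- depth %||% g$lookahead
  check_number(depth, "depth", min = 1)
  res <- cpp_lookahead_classify(g$filter$ptr, is_cascade(g), kmer,
                                as.integer(depth))
  list(kind = res$kind, surviving = as.character(res$surviving),
       n_raw = res$n_raw)
}

#' @export
print.prob_dbg <- function(x, ...) {
  cat(sprintf(
    "Probabilistic de Bruijn graph: k = %d, look-ahead = %d nodes, %s\n",
    x$k, x$lookahead,
    if (is_cascade(x)) "cascading filter (last level)" else "Bloom filter"
  ))
  invisible(x)
}
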