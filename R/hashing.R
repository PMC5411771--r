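#' Direct hash of DNA k-mers
#'
#' Computes the 64-bit forward, reverse-complement and canonical hash of
#' each k-mer from scratch.  The hash is a cyclic-polynomial (rotate/xor)
#' combination of one fixed 64-bit constant per nucleotide, with the
#' position of each base encoded by bit rotation; the canonical value is
#' `min(fwd, rc)`, identical for a k-mer and its reverse complement.
#' Values are returned as 16-digit hex strings (R has no native unsigned
#' 64-bit integer).
#'
#' @param kmers Character vector of k-mers (A/C/G/T only, any case).
#' @return A data.frame with columns `kmer`, `fwd`, `rc`, `canonical`.
#' @export
#' @examples
#' hash_kmer(c("AAAC", "GTTT"))  # same canonical value
hash_kmer <- function(kmers) {
  kmers <- as.character(kmers)
  res <- cpp_hash_kmer(kmers)
  data.frame(
    kmer = toupper(kmers), fwd = res$fwd, rc = res$rc,
    canonical = res$canonical, stringsAsFactors = FALSE
  )
}

#' Rolling hashes of all k-mer windows of a sequence
#'
#' Slides a window of length `k` along `seq`, updating the forward and
#' reverse-complement hashes in constant time per shift.  Windows that
#' contain a non-ACGT character are skipped.
#'
#' @param seq A single DNA string.
#' @param k Window length in bases.
#' @return A data.frame with columns `pos` (1-based window start), `fwd`,
#'   `rc` and `canonical` (16-digit hex strings).
#' @export
#' @examples
#' hash_kmers("ACGTACGT", k = 4)
hash_kmers <- function(seq, k) {
  check_number(k, "k", min = 1)
  res <- cpp_hash_kmers(as.character(seq)[1], as.integer(k))
  data.frame(
    pos = res$pos, fwd = res$fwd, rc = res$rc, canonical = res$canonical,
    stringsAsFactors = FALSE
  )
}

#' Multiple hash values per key without rehashing
#'
#' Derives `h` 64-bit values from each base key by a fixed arithmetic
#' schedule `value_i = base + i * g(base, seed)` with `g` a cheap
#' deterministic mixer (forced odd).  `value_0` equals the base key.  This
#' is how the Bloom filters obtain their `h` bit positions from a single
#' canonical k-mer hash.
#'
#' @param keys Keys as 16-digit hex strings or non-negative numbers below
#'   2^53.
#' @param h Number of derived values per key.
#' @param seed Integer seed entering the mixer.
#' @return A character matrix with one row per key and `h` hex columns.
#' @export
#' @examples
#' multi_hash(hash_kmer("ACGTACG")$canonical, h = 4)
multi_hash <- function(keys, h, seed = 0) {
  check_number(h, "h", min = 1, max = 64)
  check_number(seed, "seed", min = 0)
  cpp_multi_hash(keys, as.integer(h), as.numeric(seed))
}
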