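#' Create a Bloom filter
#'
#' A bit vector of `m` bits with `h` hash functions, representing a set of
#' 64-bit keys (canonical k-mer hashes).  Membership queries have no false
#' negatives; false positives occur at a rate governed by the occupancy of
#' the bit vector (see [fpr_analytic()]).  `m` is rounded up to a whole
#' byte; bit positions are the multi-hash values modulo `m`.
#'
#' @param m_bits Filter size in bits (>= 8; rounded up to a whole byte).
#' @param h Number of hash functions (default 4).
#' @param seed Hash seed (default 0).
#' @return An object of class `bloom_filter`.
#' @seealso [bf_insert()], [bf_contains()], [size_for_fpr()]
#' @export
#' @examples
#' f <- bloom_filter(1024, h = 2)
#' bf_insert(f, "00000000deadbeef")
#' bf_contains(f, "00000000deadbeef")
bloom_filter <- function(m_bits, h = 4, seed = 0) {
  check_number(m_bits, "m_bits", min = 8)
  check_number(h, "h", min = 1, max = 64)
  check_number(seed, "seed", min = 0)
  structure(
    list(ptr = cpp_bf_new(as.numeric(m_bits), as.integer(h),
                          as.numeric(seed))),
    class = "bloom_filter"
  )
}

#' Insert keys into a Bloom filter
#'
#' Sets all `h` bit positions of each key's bit signature.  Inserting a
#' key twice changes no additional bits.  The filter is modified in place;
#' the filter object is returned invisibly for chaining.
#'
#' @param f A [bloom_filter()].
#' @param keys Keys as 16-digit hex strings or non-negative numbers.
#' @return `f`, invisibly.
#' @export
bf_insert <- function(f, keys) {
  stopifnot(inherits(f, "bloom_filter"))
  cpp_bf_insert(f$ptr, keys)
  invisible(f)
}

#' Query keys against a Bloom filter
#'
#' @inheritParams bf_insert
#' @return Logical vector: `TRUE` iff every bit of the key's signature is
#'   set.  Never `FALSE` for an inserted key.
#' @export
bf_contains <- function(f, keys) {
  stopifnot(inherits(f, "bloom_filter"))
  cpp_bf_contains(f$ptr, keys)
}

#' Insert all canonical k-mers of sequences into a Bloom filter
#'
#' Convenience loader used to construct exact-content filters in tests and
#' examples: every k-mer of every ACGT segment of `seqs` is canonicalized
#' and inserted.
#'
#' @inheritParams bf_insert
#' @param seqs Character vector of DNA sequences.
#' @param k K-mer length.
#' @return Number of k-mer occurrences inserted, invisibly.
#' @export
bf_insert_kmers <- function(f, seqs, k) {
  stopifnot(inherits(f, "bloom_filter"))
  check_number(k, "k", min = 1)
  invisible(cpp_bf_insert_kmers(f$ptr, as.character(seqs), as.integer(k)))
}

#' @export
print.bloom_filter <- function(x, ...) {
  info <- cpp_bf_info(x$ptr)
  cat(sprintf(
    "Bloom filter: m = %.0f bits, h = %d, %0.f inserts, occupancy %.3f\n",
    info$m, info$h, info$inserts, info$popcount / info$m
  ))
  invisible(x)
}

bf_info <- function(f) cpp_bf_info(f$ptr)

#' Bloom filter introspection
#'
#' @param f A [bloom_filter()].
#' @return `bf_bits()`: allocated bit-vector length; `bf_popcount()`:
#'   number of set bits; `bf_inserts()`: number of insert calls.
#' @export
bf_bits <- function(f) bf_info(f)$m

#' @rdname bf_bits
#' @export
bf_popcount <- function(f) bf_info(f)$popcount

#' @rdname bf_bits
#' @export
bf_inserts <- function(f) bf_info(f)$inserts

#' Serialize a Bloom filter to a file
#'
#' Writes a small header (magic, version, m, h, k, seed, insert count)
#' followed by the raw little-endian bit vector, permitting a resumable
#' two-pass assembly.
#'
#' @param f A [bloom_filter()].
#' @param path Output file path.
#' @param k K-mer length the filter was loaded with (stored in the
#'   header; use 0 if not applicable).
#' @return `path`, invisibly.
#' @export
save_bloom <- function(f, path, k = 0) {
  info <- bf_info(f)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("BDBGBF", con, nchars = 6, eos = NULL)
  writeBin(as.integer(1), con, size = 4, endian = "little")
  for (v in c(info$m, info$h, k, info$seed, info$inserts)) {
    writeBin(as.numeric(v), con, size = 8, endian = "little")
  }
  writeBin(cpp_bf_dump(f$ptr), con)
  invisible(path)
}

#' @rdname save_bloom
#' @export
load_bloom <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 6, useBytes = TRUE)
  if (!identical(magic, "BDBGBF")) {
    stop_bloomdbg("not a serialized Bloom filter", "bloomdbg_parse_error")
  }
  version <- readBin(con, integer(), size = 4, endian = "little")
  if (version != 1) {
    stop_bloomdbg("unsupported filter version", "bloomdbg_parse_error")
  }
  hdr <- readBin(con, numeric(), n = 5, size = 8, endian = "little")
  bits <- readBin(con, raw(), n = hdr[1] / 8)
  f <- structure(
    list(ptr = cpp_bf_restore(hdr[1], as.integer(hdr[2]), hdr[4], hdr[5],
                              bits)),
    class = "bloom_filter"
  )
  attr(f, "k") <- hdr[3]
  f
}

#' Analytic Bloom filter false-positive rate
#'
#' The probability that a never-inserted key queries as present in a
#' filter of `m` bits with `h` hash functions after `n` distinct keys have
#' been inserted:
#' \deqn{FPR = (1 - (1 - 1/m)^{hn})^h \approx (1 - e^{-hn/m})^h}
#'
#' @param m Filter size in bits.
#' @param h Number of hash functions.
#' @param n Number of distinct keys inserted.
#' @param approx If `TRUE`, return the exponential approximation instead
#'   of the exact form.
#' @return False-positive probability in \[0, 1\].
#' @export
#' @examples
#' fpr_analytic(8e6, h = 1, n = 1e6)
fpr_analytic <- function(m, h, n, approx = FALSE) {
  check_number(m, "m", min = 1)
  check_number(h, "h", min = 1)
  check_number(n, "n", min = 0)
  if (approx) {
    (1 - exp(-h * n / m))^h
  } else {
    (1 - exp(h * n * log1p(-1 / m)))^h
  }
}

#' Size a Bloom filter for a target false-positive rate
#'
#' Smallest filter size `m` (rounded up to a whole byte) such that
#' `fpr_analytic(m, h, n) <= target_fpr`.
#'
#' @param n Expected number of distinct keys.
#' @param target_fpr Desired false-positive probability in (0, 1).
#' @param h Number of hash functions.
#' @return Filter size in bits (a multiple of 8).
#' @export
#' @examples
#' size_for_fpr(1e6, 0.05)
size_for_fpr <- function(n, target_fpr, h = 4) {
  check_number(n, "n", min = 0)
  check_number(h, "h", min = 1)
  if (!is.numeric(target_fpr) || length(target_fpr) != 1 ||
      is.na(target_fpr) || target_fpr <= 0 || target_fpr >= 1) {
    stop_bloomdbg("target_fpr must be in (0, 1)", "bloomdbg_parameter_error")
  }
  if (n == 0) {
    return(8)
  }
  ok <- function(m) fpr_analytic(m, h, n) <= target_fpr
  ## bracket in bytes, then bisect to the smallest admissible byte count
  hi_bytes <- max(1, ceiling(-h * n / log(1 - target_fpr^(1 / h)) / 8))
  while (!ok(hi_bytes * 8)) hi_bytes <- hi_bytes * 2
  lo_bytes <- 1
  while (lo_bytes < hi_bytes) {
    mid <- lo_bytes + (hi_bytes - lo_bytes) %/% 2
    if (ok(mid * 8)) hi_bytes <- mid else lo_bytes <- mid + 1
  }
  hi_bytes * 8
}

#' Total memory of the filter stack
#'
#' With `c` equal-sized cascade levels plus the tracking filter (sized
#' like one level), the assembler allocates `(c + 1) * per_level_bits`
#' bits in total.
#'
#' @param per_level_bits Bits per cascade level.
#' @param c Number of cascade levels (the minimum k-mer count threshold).
#' @return Total bits allocated.
#' @export
#' @examples
#' total_memory(1e6, c = 3)
total_memory <- function(per_level_bits, c) {
  check_number(per_level_bits, "per_level_bits", min = 8)
  check_number(c, "c", min = 1)
  (c + 1) * per_level_bits
}

#' Probability of a chance connection between distant k-mers
#'
#' Bloom filter false positives can join two k-mers that overlap by only
#' `o < k - 1` bases, via `k - 1 - o` consecutive false-positive k-mers.
#' The probability of such a chance connection is `fpr^(k - 1 - o)`,
#' decreasing exponentially as the overlap shrinks.
#'
#' @param fpr Bloom filter false-positive rate in \[0, 1\].
#' @param k K-mer length.
#' @param o Overlap in bases between the two k-mers (0 <= o <= k - 1).
#' @return The chance-connection probability.
#' @export
#' @examples
#' chance_connection_probability(0.05, k = 31, o = 25)  # 0.05^5
chance_connection_probability <- function(fpr, k, o) {
  check_number(fpr, "fpr", min = 0, max = 1)
  check_number(k, "k", min = 1)
  check_number(o, "o", min = 0, max = k - 1)
  fpr^(k - 1 - o)
}

#' Create a cascading Bloom filter
#'
#' A chain of `c` equal-sized Bloom filters implementing occurrence-count
#' thresholding: a key is added to the first level where it is absent, so
#' level `i` holds keys seen at least `i` times (up to false positives)
#' and the last level approximates the set of keys with count `>= c`
#' ("solid" k-mers).  All levels share hash values.
#'
#' @inheritParams bloom_filter
#' @param c Number of levels, i.e. the minimum occurrence threshold.
#' @return An object of class `cascading_bloom_filter`.
#' @export
#' @examples
#' cf <- cascading_bloom_filter(1024, c = 3)
#' cbf_insert(cf, rep("00000000deadbeef", 3))
#' cbf_solid_contains(cf, "00000000deadbeef")
cascading_bloom_filter <- function(m_bits, c, h = 4, seed = 0) {
  check_number(m_bits, "m_bits", min = 8)
  check_number(c, "c", min = 1)
  check_number(h, "h", min = 1, max = 64)
  check_number(seed, "seed", min = 0)
  structure(
    list(ptr = cpp_cbf_new(as.numeric(m_bits), as.integer(h),
                           as.numeric(seed), as.integer(c))),
    class = "cascading_bloom_filter"
  )
}

#' Insert keys into a cascading Bloom filter
#'
#' Each key is added to the first level where it is not already present;
#' repeated insertions of the same key climb the cascade one level per
#' call (in the collision-free regime).
#'
#' @param cf A [cascading_bloom_filter()].
#' @param keys Keys as 16-digit hex strings or non-negative numbers.
#' @return `cf`, invisibly.
#' @export
cbf_insert <- function(cf, keys) {
  stopifnot(inherits(cf, "cascading_bloom_filter"))
  cpp_cbf_insert(cf$ptr, keys)
  invisible(cf)
}

#' Query a cascading Bloom filter
#'
#' `cbf_solid_contains()` queries the last level only — the solid-k-mer
#' set once loading has completed.  `cbf_contains()` queries an arbitrary
#' level.
#'
#' @inheritParams cbf_insert
#' @param level Level to query (1-based; defaults to the last).
#' @return Logical vector of membership calls.
#' @export
cbf_solid_contains <- function(cf, keys) {
  stopifnot(inherits(cf, "cascading_bloom_filter"))
  cpp_cbf_contains(cf$ptr, keys, cpp_cbf_info(cf$ptr)$c)
}

#' @rdname cbf_solid_contains
#' @export
cbf_contains <- function(cf, keys, level = NULL) {
  stopifnot(inherits(cf, "cascading_bloom_filter"))
  level <- level %||% cpp_cbf_info(cf$ptr)$c
  cpp_cbf_contains(cf$ptr, keys, as.integer(level))
}

#' Cascading-filter introspection
#'
#' @param cf A [cascading_bloom_filter()].
#' @return `cbf_info()`: list with `m` (bits per level), `h`, `c`,
#'   `level_inserts` (distinct keys that landed in each level) and
#'   `level_bits`.  `cbf_bits()`: total allocated bits across levels.
#' @export
cbf_info <- function(cf) {
  stopifnot(inherits(cf, "cascading_bloom_filter"))
  cpp_cbf_info(cf$ptr)
}

#' @rdname cbf_info
#' @export
cbf_bits <- function(cf) sum(cbf_info(cf)$level_bits)

#' Free the early cascade levels
#'
#' After the loading pass only the last level (the solid-k-mer set) is
#' queried; dropping levels `1..c-1` releases their memory, mirroring the
#' peak-memory accounting of the two-pass design.
#'
#' @param cf A [cascading_bloom_filter()].
#' @return `cf`, invisibly.
#' @export
cbf_drop_early <- function(cf) {
  stopifnot(inherits(cf, "cascading_bloom_filter"))
  cpp_cbf_drop_early(cf$ptr)
  invisible(cf)
}

#' @export
print.cascading_bloom_filter <- function(x, ...) {
  info <- cbf_info(x)
  cat(sprintf(
    "Cascading Bloom filter: c = %d levels x %.0f bits, h = %d\n",
    info$c, info$m, info$h
  ))
  cat("  level inserts:", paste(format(info$level_inserts), collapse = ", "),
      "\n")
  invisible(x)
}
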