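stop_bloomdbg <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "bloomdbg_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## Coerce assorted read containers (character vector, Biostrings
## XStringSet, file path(s)) to a plain character vector of sequences.
as_read_vector <- function(reads) {
  if (methods::is(reads, "XStringSet")) {
    return(as.character(reads))
  }
  if (is.character(reads)) {
    if (length(reads) > 0 && all(file.exists(reads))) {
      return(as.character(do.call(c, lapply(reads, read_sequences))))
    }
    return(reads)
  }
  stop_bloomdbg(
    "reads must be a character vector, an XStringSet, or file path(s)",
    "bloomdbg_parameter_error"
  )
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    stop_bloomdbg(
      sprintf("%s must be a single number in [%s, %s]", name, min, max),
      "bloomdbg_parameter_error"
    )
  }
  x
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T, case-insensitive).
#' @return Character vector of reverse complements (upper case).
#' @export
#' @examples
#' revcomp("AAAC")
revcomp <- function(x) cpp_revcomp(as.character(x))

#' Canonical form of DNA sequences
#'
#' The canonical form of a sequence is the byte-wise lexicographic minimum
#' of the sequence and its reverse complement, so that a sequence and its
#' reverse complement map to the same representative.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of canonical sequences.
#' @export
#' @examples
#' canonical_sequence(c("GTTT", "AAAC"))
canonical_sequence <- function(x) cpp_canonical_sequence(as.character(x))
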