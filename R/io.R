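#' Read sequences from FASTA or FASTQ
#'
#' The format is auto-detected from the first byte (`>` for FASTA, `@`
#' for FASTQ); plain and gzip-compressed files are both accepted.
#' Record ids are the header token before the first whitespace.  Base
#' qualities are not retained — the unitig stage does not use them.
#'
#' @param path Path to a FASTA or FASTQ file (optionally .gz).
#' @return A [Biostrings::DNAStringSet] named by record id.
#' @export
read_sequences <- function(path) {
  path <- as.character(path)[1]
  if (!file.exists(path)) {
    stop_bloomdbg(sprintf("file not found: %s", path), "bloomdbg_io_error")
  }
  con <- gzfile(path, "rb")
  first <- readChar(con, 1, useBytes = TRUE)
  close(con)
  if (length(first) == 0 || !nzchar(first)) {
    return(Biostrings::DNAStringSet())
  }
  fmt <- switch(first, ">" = "fasta", "@" = "fastq", NA_character_)
  if (is.na(fmt)) {
    stop_bloomdbg(
      sprintf("%s: first byte '%s' is neither '>' (FASTA) nor '@' (FASTQ)",
              path, first),
      "bloomdbg_parse_error"
    )
  }
  if (fmt == "fastq") validate_fastq(path)
  res <- tryCatch(
    Biostrings::readDNAStringSet(path, format = fmt),
    error = function(e) {
      stop_bloomdbg(
        sprintf("failed to parse %s as %s: %s", path, toupper(fmt),
                conditionMessage(e)),
        "bloomdbg_parse_error"
      )
    }
  )
  names(res) <- sub("\\s.*$", "", names(res))
  res
}

## Streaming structural check of a FASTQ file (constant memory): records
## are groups of four lines (@id, sequence, +, quality) and the quality
## string must match the sequence length.  Errors carry the line number.
validate_fastq <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  lineno <- 0
  buf <- character(0)
  fail <- function(msg, at) {
    stop_bloomdbg(sprintf("%s: %s at line %d", path, msg, at),
                  "bloomdbg_parse_error")
  }
  repeat {
    chunk <- readLines(con, n = 40000L)
    if (length(chunk) == 0 && length(buf) == 0) break
    buf <- c(buf, chunk)
    n_rec <- length(buf) %/% 4L
    if (n_rec > 0) {
      idx <- seq_len(n_rec * 4L)
      rec <- matrix(buf[idx], nrow = 4L)
      base <- lineno
      bad_id <- which(!startsWith(rec[1, ], "@"))
      if (length(bad_id)) {
        fail("record header does not start with '@'",
             base + (bad_id[1] - 1) * 4 + 1)
      }
      bad_sep <- which(!startsWith(rec[3, ], "+"))
      if (length(bad_sep)) {
        fail("separator line does not start with '+'",
             base + (bad_sep[1] - 1) * 4 + 3)
      }
      bad_q <- which(nchar(rec[4, ]) != nchar(rec[2, ]))
      if (length(bad_q)) {
        fail("quality length does not match sequence length",
             base + (bad_q[1] - 1) * 4 + 4)
      }
      lineno <- lineno + n_rec * 4L
      buf <- buf[-idx]
    }
    if (length(chunk) == 0) {
      if (length(buf)) fail("truncated record", lineno + 1)
      break
    }
  }
  invisible(TRUE)
}

#' Write unitigs to FASTA
#'
#' Headers have the form `>unitig_<id> len=<length> seed=<seed_id>`;
#' sequences are wrapped at 80 columns and written in assembly order, so
#' output is deterministic.
#'
#' @param x A `unitig_assembly` (see [assemble()]) or a character vector
#'   of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_unitigs <- function(x, path) {
  if (inherits(x, "unitig_assembly")) {
    seqs <- x$unitigs
    seeds <- x$seed_read
  } else {
    seqs <- as.character(x)
    seeds <- rep(NA_integer_, length(seqs))
  }
  lines <- character(0)
  if (length(seqs)) {
    lines <- unlist(lapply(seq_along(seqs), function(i) {
      s <- seqs[[i]]
      hdr <- sprintf(">unitig_%d len=%d seed=%s", i, nchar(s),
                     ifelse(is.na(seeds[i]), "NA", seeds[i]))
      starts <- seq(1, nchar(s), by = 80)
      c(hdr, substring(s, starts, pmin(starts + 79, nchar(s))))
    }))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
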