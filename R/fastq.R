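#' Read a FASTQ file into a reads tibble
#'
#' Strict 4-line-record FASTQ reader (Phred+33), accepting plain or
#' gzip-compressed input transparently. The read id is the header up to the
#' first whitespace. Each record is validated: header must start with `@`,
#' separator line with `+`, sequence and quality must have equal length, and
#' quality characters must be printable ASCII (`!`..`~`). Violations raise
#' an error naming the offending line number (and read id where known).
#'
#' @param path Path to a `.fastq` or `.fastq.gz` file.
#' @return A tibble with columns `read_id`, `seq`, `qual` (`qual` is the
#'   raw Phred+33 string; see [phred_scores()]).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  if (n == 0L) {
    return(tibble::tibble(read_id = character(), seq = character(),
                          qual = character()))
  }
  if (n %% 4L != 0L) {
    stop("truncated FASTQ: ", n, " lines is not a multiple of 4 (near line ",
         n, ")", call. = FALSE)
  }
  hdr <- lines[seq(1L, n, by = 4L)]
  seqs <- lines[seq(2L, n, by = 4L)]
  sep <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad) > 0L) {
    stop("malformed FASTQ header at line ", (bad[1L] - 1L) * 4L + 1L,
         call. = FALSE)
  }
  bad <- which(substr(sep, 1L, 1L) != "+")
  if (length(bad) > 0L) {
    stop("malformed FASTQ separator at line ", (bad[1L] - 1L) * 4L + 3L,
         call. = FALSE)
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad) > 0L) {
    stop("sequence/quality length mismatch for read ", sQuote(ids[bad[1L]]),
         " at line ", (bad[1L] - 1L) * 4L + 4L, call. = FALSE)
  }
  bad <- which(grepl("[^!-~]", qual))
  if (length(bad) > 0L) {
    stop("non-ASCII quality character for read ", sQuote(ids[bad[1L]]),
         " at line ", (bad[1L] - 1L) * 4L + 4L, call. = FALSE)
  }
  tibble::tibble(read_id = ids, seq = seqs, qual = qual)
}

#' Write a reads tibble as FASTQ
#'
#' @param reads A tibble with columns `read_id`, `seq`, `qual`.
#' @param path Output path; gzip-compressed when it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)))
  rec <- paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", reads$qual)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(rec, con, sep = "\n")
  invisible(path)
}

#' Decode Phred+33 quality strings
#'
#' @param qual Character vector of Phred+33 quality strings.
#' @return A list of integer vectors of per-base Phred scores.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(s) utf8ToInt(s) - 33L)
}
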