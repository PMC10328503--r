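#' Molecule pools
#'
#' A molecule pool records barcode abundances at one stage of the generative
#' process: the synthesized oligo library, the injection mix after PCR, the
#' extrachromosomal array, or the set of genomic integrants. It is a tibble
#' with columns `barcode` (character) and `count` (positive numeric,
#' molecule-equivalents), plus a `stage` attribute.
#'
#' @param barcode Character vector of barcode sequences (unique).
#' @param count Positive numeric abundances, same length as `barcode`.
#' @param stage One of `"library"`, `"injection_mix"`, `"array"`,
#'   `"integrants"`.
#' @return A tibble of class `molecule_pool` with columns `barcode`, `count`.
#' @export
molecule_pool <- function(barcode, count,
                          stage = c("library", "injection_mix", "array",
                                    "integrants")) {
  stage <- match.arg(stage)
  stopifnot(is.character(barcode), is.numeric(count),
            length(barcode) == length(count))
  if (anyDuplicated(barcode)) {
    stop("barcodes in a pool must be unique", call. = FALSE)
  }
  if (any(count <= 0)) {
    stop("all pool abundances must be positive", call. = FALSE)
  }
  out <- tibble::tibble(barcode = barcode, count = as.numeric(count))
  class(out) <- c("molecule_pool", class(out))
  attr(out, "stage") <- stage
  out
}

#' @export
print.molecule_pool <- function(x, ...) {
  cat("<molecule_pool> stage: ", attr(x, "stage"),
      ", ", nrow(x), " barcodes, ",
      format(sum(x$count), big.mark = ","), " molecules\n", sep = "")
  NextMethod()
}

#' Barcode frequencies of a pool
#'
#' @param pool A [molecule_pool()].
#' @return Numeric vector of frequencies (abundance / total), summing to 1.
#' @export
pool_frequencies <- function(pool) {
  stopifnot(inherits(pool, "molecule_pool"))
  pool$count / sum(pool$count)
}

pool_stage <- function(pool) attr(pool, "stage")

#' Write / read a pool snapshot as TSV
#'
#' Snapshots have columns `barcode`, `count`, `frequency` and use Unix
#' newlines with no quoting.
#'
#' @param pool A [molecule_pool()].
#' @param path File path.
#' @param stage Stage label to restore on read.
#' @return `write_pool_tsv` returns `path` invisibly; `read_pool_tsv` a
#'   [molecule_pool()].
#' @export
write_pool_tsv <- function(pool, path) {
  stopifnot(inherits(pool, "molecule_pool"))
  df <- data.frame(barcode = pool$barcode, count = pool$count,
                   frequency = pool_frequencies(pool))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' @rdname write_pool_tsv
#' @export
read_pool_tsv <- function(path, stage = "library") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  molecule_pool(df$barcode, df$count, stage = stage)
}
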