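#' Degenerate barcode template
#'
#' A barcode template is a short DNA pattern over `A`, `C`, `G`, `T`, `N`
#' in which `N` marks a randomized ("free") position and a literal base marks
#' a fixed position. The default `NNNCNNTNTNANNNN` is a 15-mer with 11 free
#' positions and four hard-coded bases (C, T, T, A at positions 4, 7, 9, 11),
#' giving a theoretical space of \eqn{4^{11} \approx 4.2} million barcodes.
#'
#' @param pattern Character scalar over `{A,C,G,T,N}`.
#'
#' @return An object of class `barcode_template`: a list with `pattern`,
#'   `length`, `free_positions` (1-based indices of `N`s) and
#'   `fixed_positions` (a data frame of 1-based `position` and `base`).
#' @examples
#' tpl <- barcode_template()
#' tpl$length            # 15
#' length(tpl$free_positions)  # 11
#' enumerate_space(tpl)  # 4194304
#' @export
barcode_template <- function(pattern = "NNNCNNTNTNANNNN") {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    stop("invalid template: symbol(s) ", paste(sQuote(bad), collapse = ", "),
         " not in {A,C,G,T,N}", call. = FALSE)
  }
  free <- which(chars == "N")
  fixed <- which(chars != "N")
  structure(
    list(
      pattern = pattern,
      length = length(chars),
      free_positions = free,
      fixed_positions = data.frame(position = fixed, base = chars[fixed],
                                   stringsAsFactors = FALSE)
    ),
    class = "barcode_template"
  )
}

#' @export
print.barcode_template <- function(x, ...) {
  cat("<barcode_template> ", x$pattern, "\n", sep = "")
  cat("  length: ", x$length, ", free positions: ", length(x$free_positions),
      ", space size: ", format(enumerate_space(x), big.mark = ","), "\n",
      sep = "")
  invisible(x)
}

#' Size of the barcode space
#'
#' Number of distinct sequences a template can produce: \eqn{4^{k}} for a
#' template with \eqn{k} free positions.
#'
#' @param template A [barcode_template()].
#' @return A numeric scalar, `4^length(free_positions)`.
#' @examples
#' enumerate_space(barcode_template("NN"))    # 16
#' enumerate_space(barcode_template("ACGT"))  # 1
#' @export
enumerate_space <- function(template) {
  stopifnot(inherits(template, "barcode_template"))
  4^length(template$free_positions)
}

#' Enumerate all sequences of a small barcode space
#'
#' Deterministically lists every sequence the template can produce, in
#' lexicographic order of the free positions (A < C < G < T). Intended for
#' small spaces; refuses to materialize more than `max_size` sequences.
#'
#' @param template A [barcode_template()].
#' @param max_size Upper bound on the number of sequences to materialize.
#' @return Character vector of length `enumerate_space(template)`.
#' @export
barcode_space <- function(template, max_size = 2^20) {
  stopifnot(inherits(template, "barcode_template"))
  n <- enumerate_space(template)
  if (n > max_size) {
    stop("space of size ", n, " exceeds max_size = ", max_size, call. = FALSE)
  }
  barcode_from_index(template, seq_len(n))
}

# Map 1-based indices in [1, 4^k] to sequences: index - 1 written in base 4
# over the free positions (most significant digit = first free position).
barcode_from_index <- function(template, index) {
  k <- length(template$free_positions)
  chars <- strsplit(template$pattern, "", fixed = TRUE)[[1L]]
  out <- matrix(rep(chars, each = length(index)), nrow = length(index))
  idx0 <- index - 1
  bases <- c("A", "C", "G", "T")
  if (k > 0L) {
    for (j in seq_len(k)) {
      digit <- (idx0 %/% 4^(k - j)) %% 4
      out[, template$free_positions[j]] <- bases[digit + 1]
    }
  }
  apply(out, 1L, paste, collapse = "")
}
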