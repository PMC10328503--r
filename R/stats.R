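#' Plateau-based read-count threshold
#'
#' Chooses the minimum read count per barcode at which the number of
#' observed unique barcodes stabilizes. Let \eqn{u(c)} be the number of
#' barcodes with count \eqn{\ge c}; the threshold is the smallest
#' \eqn{c \ge 1} with \eqn{(u(c) - u(c + k))/u(c) < } `tol`. If no plateau
#' is found for \eqn{c} up to the 99th percentile of counts, the
#' conservative `default_threshold` is returned with `plateau_found =
#' FALSE`.
#'
#' @param counts Numeric vector of per-barcode read counts (or a tibble
#'   with a `count` column).
#' @param window Plateau look-ahead `k` in count units (default 3).
#' @param tol Relative change below which `u` is considered flat
#'   (default 0.01).
#' @param default_threshold Fallback when no plateau is found (default 5).
#' @return A list with `threshold` (integer), `plateau_found` (logical) and
#'   `curve` (tibble `cutoff`, `n_unique`).
#' @export
select_threshold <- function(counts, window = 3L, tol = 0.01,
                             default_threshold = 5L) {
  if (is.data.frame(counts)) counts <- counts$count
  if (length(counts) == 0L) stop("empty counts", call. = FALSE)
  stopifnot(window >= 1, tol > 0, all(counts >= 1))
  cmax <- as.integer(quantile(counts, 0.99, type = 1L))
  u <- function(c) sum(counts >= c)
  cutoffs <- seq_len(max(cmax, 1L) + window)
  uvals <- vapply(cutoffs, u, numeric(1L))
  threshold <- NA_integer_
  for (c in seq_len(max(cmax, 1L))) {
    uc <- uvals[c]
    if (uc == 0) break
    if ((uc - uvals[c + window]) / uc < tol) {
      threshold <- c
      break
    }
  }
  plateau_found <- !is.na(threshold)
  if (!plateau_found) {
    warning("no unique-barcode plateau found; using default threshold ",
            default_threshold, call. = FALSE)
    threshold <- as.integer(default_threshold)
  }
  list(threshold = as.integer(threshold), plateau_found = plateau_found,
       curve = tibble::tibble(cutoff = cutoffs, n_unique = uvals))
}

#' Thresholded sample profile
#'
#' Applies a read-count threshold to per-barcode counts and computes
#' barcode frequencies among the surviving set.
#'
#' @param counts Tibble with columns `barcode`, `count`.
#' @param threshold Minimum count to keep a barcode (default 5).
#' @param sample_id Optional sample label.
#' @return A tibble of class `sample_profile` with columns `barcode`,
#'   `count`, `freq`, and attributes `sample_id`, `threshold`,
#'   `n_reads_total` (pre-threshold).
#' @export
sample_profile <- function(counts, threshold = 5L, sample_id = NULL) {
  stopifnot(all(c("barcode", "count") %in% names(counts)))
  total <- sum(counts$count)
  kept <- counts[counts$count >= threshold, , drop = FALSE]
  out <- tibble::tibble(barcode = kept$barcode, count = kept$count,
                        freq = kept$count / sum(kept$count))
  class(out) <- c("sample_profile", class(out))
  attr(out, "sample_id") <- sample_id
  attr(out, "threshold") <- as.integer(threshold)
  attr(out, "n_reads_total") <- total
  out
}

#' Diversity summary of a profile
#'
#' @param profile A [sample_profile()] (or any tibble with `count`, `freq`).
#' @return A tibble with `n_unique`, `n_reads`, `max_freq`, `min_freq`,
#'   `freq_cv` (coefficient of variation of frequencies, 0 for a single
#'   barcode).
#' @export
summarize_diversity <- function(profile) {
  f <- profile$freq
  cv <- if (length(f) < 2L) 0 else sd(f) / mean(f)
  tibble::tibble(
    n_unique = nrow(profile),
    n_reads = sum(profile$count),
    max_freq = max(f),
    min_freq = min(f),
    freq_cv = cv
  )
}

#' Jackpot report
#'
#' Identifies overrepresented ("jackpotted") barcodes in raw, pre-threshold
#' counts: those with counts strictly greater than `cutoff`, together with
#' the fraction of all reads they carry and the fraction of unique barcodes
#' they represent.
#'
#' @param counts Tibble with columns `barcode`, `count` (pre-threshold).
#' @param cutoff Count cutoff (default 50).
#' @return A list with `barcodes` (character), `n_jackpot`,
#'   `reads_fraction`, `unique_fraction`.
#' @export
jackpot_report <- function(counts, cutoff = 50L) {
  stopifnot(all(c("barcode", "count") %in% names(counts)), cutoff >= 1)
  hit <- counts$count > cutoff
  list(
    barcodes = counts$barcode[hit],
    n_jackpot = sum(hit),
    reads_fraction = if (any(hit)) sum(counts$count[hit]) / sum(counts$count)
                     else 0,
    unique_fraction = if (nrow(counts) > 0L) sum(hit) / nrow(counts) else 0
  )
}

#' Position probability matrix of a barcode set
#'
#' Per-position base probabilities over equal-length barcodes, as plotted in
#' sequence logos. With `weighting = "unique"` each barcode counts once;
#' with `"read_weighted"` each barcode is weighted by its frequency.
#'
#' @param profile A [sample_profile()] or tibble with `barcode` (and `freq`
#'   for read weighting), or a bare character vector of barcodes.
#' @param weighting `"unique"` (default) or `"read_weighted"`.
#' @return A 4 x L column-stochastic matrix with rows `A`, `C`, `G`, `T`.
#' @export
position_probabilities <- function(profile,
                                   weighting = c("unique", "read_weighted")) {
  weighting <- match.arg(weighting)
  barcodes <- if (is.character(profile)) profile else profile$barcode
  if (length(barcodes) == 0L) stop("no barcodes", call. = FALSE)
  L <- unique(nchar(barcodes))
  if (length(L) != 1L) stop("mixed barcode lengths", call. = FALSE)
  w <- if (weighting == "unique") {
    rep(1 / length(barcodes), length(barcodes))
  } else {
    stopifnot(!is.character(profile), "freq" %in% names(profile))
    profile$freq / sum(profile$freq)
  }
  ch <- matrix(unlist(strsplit(barcodes, "", fixed = TRUE), use.names = FALSE),
               ncol = L, byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  out <- vapply(seq_len(L), function(j) {
    vapply(bases, function(b) sum(w[ch[, j] == b]), numeric(1L))
  }, numeric(4L))
  # renormalize columns in case of N's (excluded from the four rows)
  out <- sweep(out, 2L, colSums(out), "/")
  rownames(out) <- bases
  colnames(out) <- as.character(seq_len(L))
  out
}

#' Cross-sample barcode overlap
#'
#' For two or more barcode sets, tabulates how many barcodes of the union
#' occur in exactly 1, 2, ..., n sets, and the directional containment
#' \eqn{|A \cap B| / |A|} for every ordered pair.
#'
#' @param sets Named list (length >= 2) of character vectors.
#' @return A list with `membership` (tibble `n_sets`, `n_barcodes`, `pct`),
#'   `n_union`, and `containment` (matrix, `containment[i, j]` =
#'   fraction of set i also found in set j).
#' @export
overlap_analysis <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  sets <- lapply(sets, unique)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  k <- rowSums(member)
  tab <- tabulate(k, nbins = length(sets))
  membership <- tibble::tibble(
    n_sets = seq_along(sets),
    n_barcodes = tab,
    pct = 100 * tab / length(universe)
  )
  n <- length(sets)
  containment <- matrix(NA_real_, n, n,
                        dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      containment[i, j] <- length(intersect(sets[[i]], sets[[j]])) /
        length(sets[[i]])
    }
  }
  list(membership = membership, n_union = length(universe),
       containment = containment)
}

# Invert m = lambda / (1 - exp(-lambda)) by safeguarded Newton iteration.
ztpois_lambda_from_mean <- function(m, tol = 1e-10, max_iter = 100L) {
  stopifnot(m >= 1)
  if (m <= 1 + 1e-12) return(0)
  lo <- 0
  hi <- m            # lambda <= mean always
  lambda <- m - exp(-m) * m   # decent start, exact as m grows
  for (iter in seq_len(max_iter)) {
    em <- exp(-lambda)
    g <- lambda / (1 - em) - m
    if (g > 0) hi <- lambda else lo <- lambda
    gp <- (1 - em - lambda * em) / (1 - em)^2
    step <- g / gp
    cand <- lambda - step
    if (!is.finite(cand) || cand <= lo || cand >= hi) {
      cand <- (lo + hi) / 2
    }
    if (abs(cand - lambda) < tol) return(cand)
    lambda <- cand
  }
  lambda
}

#' Fit a zero-truncated Poisson to copy counts
#'
#' Maximum-likelihood fit of a zero-truncated Poisson (Poisson conditioned
#' on being >= 1) to positive integer counts. The MLE solves
#' \eqn{\lambda / (1 - e^{-\lambda}) = \bar{x}} and is found by safeguarded
#' Newton iteration (tolerance 1e-10). Goodness of fit is a chi-square test
#' with right-tail bins merged until every expected count is >= 5 (degrees
#' of freedom: bins - 2). A sample mean <= 1 puts the MLE on the
#' \eqn{\lambda \to 0} boundary; the fit is reported with `boundary = TRUE`
#' and the GOF is skipped.
#'
#' @param x Positive integer counts (copy numbers).
#' @return A list with `lambda`, `mean`, `boundary`, `gof_stat`, `gof_df`,
#'   `p_value` (`NA` when the GOF is not computable).
#' @export
fit_zt_poisson <- function(x) {
  stopifnot(length(x) > 0L, all(x >= 1), all(x == round(x)))
  m <- mean(x)
  if (m <= 1 + 1e-12) {
    return(list(lambda = 0, mean = m, boundary = TRUE,
                gof_stat = NA_real_, gof_df = NA_integer_,
                p_value = NA_real_))
  }
  lambda <- ztpois_lambda_from_mean(m)
  n <- length(x)
  kmax <- max(x)
  p <- dpois(seq_len(kmax), lambda) / (1 - exp(-lambda))
  p[kmax] <- p[kmax] + max(0, 1 - sum(p))  # fold the upper tail in
  expected <- n * p
  observed <- tabulate(x, nbins = kmax)
  # merge right-tail bins until all expected >= 5
  while (length(expected) > 2L && expected[length(expected)] < 5) {
    k <- length(expected)
    expected[k - 1L] <- expected[k - 1L] + expected[k]
    observed[k - 1L] <- observed[k - 1L] + observed[k]
    expected <- expected[-k]
    observed <- observed[-k]
  }
  if (length(expected) < 3L || any(expected < 5)) {
    return(list(lambda = lambda, mean = m, boundary = FALSE,
                gof_stat = NA_real_, gof_df = NA_integer_,
                p_value = NA_real_))
  }
  stat <- sum((observed - expected)^2 / expected)
  df <- length(expected) - 2L
  list(lambda = lambda, mean = m, boundary = FALSE,
       gof_stat = stat, gof_df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}
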