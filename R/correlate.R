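# Two-sided Pearson p-value computed in log space so that extreme
# correlations (p ~ 1e-154) don't underflow before they can be reported.
pearson_p <- function(r, n) {
  if (n < 3L) return(list(p = NA_real_, log10_p = NA_real_))
  if (abs(r) >= 1) return(list(p = 0, log10_p = -Inf))
  t <- abs(r) * sqrt((n - 2) / (1 - r^2))
  log_p <- log(2) + pt(t, df = n - 2, lower.tail = FALSE, log.p = TRUE)
  list(p = exp(log_p), log10_p = log_p / log(10))
}

zero_fill <- function(profile, universe) {
  f <- stats::setNames(rep(0, length(universe)), universe)
  common <- profile$barcode %in% universe
  f[profile$barcode[common]] <- profile$freq[common]
  as.numeric(f)
}

# Sequential (peeling) studentized-residual outlier detection for one
# replicate: flag the most extreme externally studentized residual above z,
# refit without flagged points, repeat. Peeling avoids masking, where one
# gross outlier inflates the residual scale and hides a second one.
detect_outliers_one <- function(x, y, z, max_frac = 0.2) {
  n <- length(x)
  flagged <- logical(n)
  repeat {
    fit <- lm(y ~ x, subset = which(!flagged))
    if (stats::sigma(fit) <= 1e-12 * max(abs(y), 1)) break  # exact fit
    rs <- rep(0, n)
    rs[!flagged] <- rstudent(fit)
    rs[!is.finite(rs)] <- 0
    cand <- which(!flagged & abs(rs) > z)
    if (length(cand) == 0L || sum(flagged) >= max_frac * n) break
    flagged[cand[which.max(abs(rs[cand]))]] <- TRUE
  }
  # residuals of every point from the final (outlier-free) fit
  res <- y - (stats::coef(fit)[1] + stats::coef(fit)[2] * x)
  list(flagged = flagged, residual = res)
}

#' Array-versus-F1 frequency correlation with replicated outliers
#'
#' Correlates barcode frequencies in an array profile with the frequencies
#' of the same barcodes among F1 integrants, per replicate and pooled.
#' The barcode universe is either the union of array and replicate barcode
#' sets with absent barcodes zero-filled (default) or the intersection.
#' Pearson r is computed per replicate and on the pooled point set (all
#' replicates' points concatenated, as when all replicates are drawn on one
#' scatter); the mean per-replicate r is also reported. Two-sided p-values
#' come from the t transform of r evaluated in log space, so extreme values
#' are reported as finite `log10_p` rather than underflowing.
#'
#' Outliers — barcodes integrating more or less often than their array
#' frequency predicts — are detected per replicate from the least-squares
#' fit of integrant on array frequency by sequential deletion: the point
#' with the largest externally studentized residual above `outlier_z` is
#' flagged, the line is refit without flagged points, and the step repeats
#' until no residual exceeds the cutoff (at most 20% of points can be
#' flagged). Peeling prevents a gross outlier from masking a smaller one by
#' inflating the residual scale. A barcode is a *replicated* outlier when
#' flagged in at least `outlier_min_replicates` replicates, and is labeled
#' over- or under-integrating by the sign of its mean residual from the
#' outlier-free fits.
#'
#' @param array_profile A [sample_profile()] (or tibble with `barcode`,
#'   `freq`) for the array.
#' @param f1_profiles List of profiles (one per biological replicate).
#' @param universe `"union_zero_fill"` (default) or `"intersection"`.
#' @param outlier_z Studentized-residual cutoff (default 3).
#' @param outlier_min_replicates Minimum replicates flagging a barcode
#'   (default 3).
#' @return A list with `per_replicate` (tibble `replicate`, `n`, `r`, `p`,
#'   `log10_p`), `pooled` (list `r`, `p`, `log10_p`, `n`),
#'   `mean_replicate_r`, and `outliers` (tibble `barcode`, `n_flagged`,
#'   `direction`, `mean_residual`).
#' @export
array_f1_correlation <- function(array_profile, f1_profiles,
                                 universe = c("union_zero_fill",
                                              "intersection"),
                                 outlier_z = 3,
                                 outlier_min_replicates = 3L) {
  universe <- match.arg(universe)
  stopifnot(length(f1_profiles) >= 1L, outlier_z > 0)
  if (inherits(f1_profiles, "sample_profile") ||
      !is.null(f1_profiles$barcode)) {
    f1_profiles <- list(f1_profiles)
  }
  barcode_sets <- c(list(array_profile$barcode),
                    lapply(f1_profiles, `[[`, "barcode"))
  uni <- if (universe == "union_zero_fill") {
    sort(unique(unlist(barcode_sets)))
  } else {
    sort(Reduce(intersect, barcode_sets))
  }
  if (length(uni) < 3L) {
    stop("fewer than 3 barcodes in the correlation universe", call. = FALSE)
  }
  x <- zero_fill(array_profile, uni)

  n_rep <- length(f1_profiles)
  per_rep <- vector("list", n_rep)
  flags <- matrix(FALSE, nrow = length(uni), ncol = n_rep)
  resid_mat <- matrix(NA_real_, nrow = length(uni), ncol = n_rep)
  xs <- ys <- numeric(0)
  for (k in seq_len(n_rep)) {
    y <- zero_fill(f1_profiles[[k]], uni)
    r <- cor(x, y)
    pv <- pearson_p(r, length(uni))
    per_rep[[k]] <- tibble::tibble(replicate = k, n = length(uni), r = r,
                                   p = pv$p, log10_p = pv$log10_p)
    det <- detect_outliers_one(x, y, outlier_z)
    flags[, k] <- det$flagged
    resid_mat[, k] <- det$residual
    xs <- c(xs, x)
    ys <- c(ys, y)
  }
  pooled_r <- cor(xs, ys)
  pooled_p <- pearson_p(pooled_r, length(xs))
  n_flag <- rowSums(flags)
  hit <- which(n_flag >= outlier_min_replicates)
  mean_res <- rowMeans(resid_mat)
  outliers <- tibble::tibble(
    barcode = uni[hit],
    n_flagged = n_flag[hit],
    direction = ifelse(mean_res[hit] > 0, "over", "under"),
    mean_residual = mean_res[hit]
  )
  per_replicate <- dplyr::bind_rows(per_rep)
  list(
    per_replicate = per_replicate,
    pooled = list(r = pooled_r, p = pooled_p$p, log10_p = pooled_p$log10_p,
                  n = length(xs)),
    mean_replicate_r = mean(per_replicate$r),
    outliers = outliers
  )
}
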