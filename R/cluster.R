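#' Capped Levenshtein edit distance
#'
#' Exact Levenshtein (substitution/insertion/deletion) distance between `a`
#' and each element of `b`, computed with a banded dynamic program that
#' exits early once the distance is known to exceed `cap`; distances above
#' the cap are reported as `cap + 1`.
#'
#' @param a Character scalar.
#' @param b Character vector.
#' @param cap Integer cap (>= 0); pass a large value for uncapped distances.
#' @return Integer vector: `min(d(a, b_i), cap + 1)`.
#' @examples
#' edit_distance("ACGT", c("ACGT", "ACGA", "AGT"), cap = 2)
#' @export
edit_distance <- function(a, b, cap = 10L) {
  stopifnot(is.character(a), length(a) == 1L, is.character(b), cap >= 0)
  edit_distance_cpp(a, b, as.integer(cap))
}

#' Error-correct barcode counts by abundance-greedy sphere clustering
#'
#' Sequences are visited in order of decreasing count (ties broken
#' lexicographically). Each sequence joins the nearest existing centroid
#' whose Levenshtein distance is at most `radius` and whose own input count
#' is at least `merge_ratio` times the sequence's count (ties: nearest
#' distance, then highest centroid count, then lexicographically smallest
#' centroid); otherwise it founds a new centroid. After clustering,
#' centroids whose length differs from `required_length` are dropped with
#' their aggregated mass. Total input count always equals centroid mass
#' plus dropped mass.
#'
#' @param counts Tibble or data frame with columns `barcode`, `count`
#'   (positive).
#' @param radius Edit-distance bound for absorption (default 2).
#' @param merge_ratio Minimum centroid-to-member count ratio (default 5).
#' @param required_length Centroid length filter (default 15); `NULL`
#'   disables it.
#' @return A list of class `cluster_result` with `centroids` (tibble
#'   `centroid`, `count`, sorted by count), `assignments` (tibble `barcode`,
#'   `centroid`, `distance`, `count`) and `dropped` (tibble `barcode`,
#'   `count` of length-filtered centroids, with their absorbed mass).
#' @examples
#' cluster_barcodes(data.frame(barcode = c("AAAAA", "AAAAT"),
#'                             count = c(100, 2)),
#'                  radius = 1, required_length = 5)
#' @export
cluster_barcodes <- function(counts, radius = 2L, merge_ratio = 5,
                             required_length = 15L) {
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  if (merge_ratio < 1) stop("merge_ratio must be >= 1", call. = FALSE)
  stopifnot(all(c("barcode", "count") %in% names(counts)),
            all(counts$count > 0))
  ord <- order(-counts$count, counts$barcode)
  seqs <- counts$barcode[ord]
  cnt <- as.numeric(counts$count[ord])
  n <- length(seqs)

  cent_seq <- character(0)
  cent_seed <- numeric(0)   # centroid's own input count (merge gate)
  cent_mass <- numeric(0)   # aggregated mass
  cent_len <- integer(0)
  assign_to <- integer(n)
  assign_d <- integer(n)

  for (i in seq_len(n)) {
    target <- 0L
    best_d <- radius + 1L
    if (length(cent_seq) > 0L && radius > 0L) {
      cand <- which(cent_seed >= merge_ratio * cnt[i] &
                      abs(cent_len - nchar(seqs[i])) <= radius)
      if (length(cand) > 0L) {
        d <- edit_distance_cpp(seqs[i], cent_seq[cand], as.integer(radius))
        ok <- d <= radius
        if (any(ok)) {
          cand <- cand[ok]
          d <- d[ok]
          o <- order(d, -cent_seed[cand], cent_seq[cand])[1L]
          target <- cand[o]
          best_d <- d[o]
        }
      }
    }
    if (target > 0L) {
      cent_mass[target] <- cent_mass[target] + cnt[i]
      assign_to[i] <- target
      assign_d[i] <- best_d
    } else {
      cent_seq <- c(cent_seq, seqs[i])
      cent_seed <- c(cent_seed, cnt[i])
      cent_mass <- c(cent_mass, cnt[i])
      cent_len <- c(cent_len, nchar(seqs[i]))
      assign_to[i] <- length(cent_seq)
      assign_d[i] <- 0L
    }
  }

  keep <- if (is.null(required_length)) {
    rep(TRUE, length(cent_seq))
  } else {
    cent_len == required_length
  }
  centroids <- tibble::tibble(centroid = cent_seq[keep],
                              count = cent_mass[keep]) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$centroid)
  dropped <- tibble::tibble(barcode = cent_seq[!keep],
                            count = cent_mass[!keep])
  assignments <- tibble::tibble(barcode = seqs,
                                centroid = cent_seq[assign_to],
                                distance = assign_d,
                                count = cnt)
  structure(list(centroids = centroids, assignments = assignments,
                 dropped = dropped),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", nrow(x$centroids), " centroids (",
      format(sum(x$centroids$count), big.mark = ","), " counts), ",
      nrow(x$dropped), " length-filtered (",
      format(sum(x$dropped$count), big.mark = ","), " counts)\n", sep = "")
  invisible(x)
}

#' Write a cluster map as TSV
#'
#' @param result A [cluster_barcodes()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(result, path) {
  stopifnot(inherits(result, "cluster_result"))
  utils::write.table(as.data.frame(result$assignments), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}
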