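# Independent oracles and small fixture builders used across test files.

# Brute-force greedy sphere clustering over the full utils::adist matrix,
# implementing the documented rule directly: visit sequences by decreasing
# count (ties lexicographic); join the nearest centroid within `radius`
# whose own input count is >= ratio * count (ties: distance, then centroid
# count, then lexicographic); else found a new centroid; then drop
# centroids of the wrong length with their mass.
oracle_cluster <- function(counts, radius, merge_ratio, required_length) {
  ord <- order(-counts$count, counts$barcode)
  seqs <- counts$barcode[ord]
  cnt <- counts$count[ord]
  d <- utils::adist(seqs, seqs)
  centroids <- integer(0)   # indices into seqs
  mass <- numeric(0)
  assign_to <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    best <- 0L
    if (length(centroids) > 0L) {
      cand <- centroids[d[i, centroids] <= radius &
                          cnt[centroids] >= merge_ratio * cnt[i]]
      if (length(cand) > 0L) {
        o <- order(d[i, cand], -cnt[cand], seqs[cand])
        best <- cand[o[1L]]
      }
    }
    if (best > 0L) {
      mass[match(best, centroids)] <- mass[match(best, centroids)] + cnt[i]
      assign_to[i] <- best
    } else {
      centroids <- c(centroids, i)
      mass <- c(mass, cnt[i])
      assign_to[i] <- i
    }
  }
  keep <- if (is.null(required_length)) rep(TRUE, length(centroids)) else
    nchar(seqs[centroids]) == required_length
  out <- data.frame(centroid = seqs[centroids[keep]], count = mass[keep],
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$centroid), , drop = FALSE]
}

# Plain scanning oracle for UMI block location: first start position where
# both flanks match exactly.
oracle_umi <- function(seq, f5 = "CAC", ulen = 10L, f3 = "GAC") {
  block <- nchar(f5) + ulen + nchar(f3)
  L <- nchar(seq)
  if (L >= block) {
    for (s in seq_len(L - block + 1L)) {
      if (substr(seq, s, s + nchar(f5) - 1L) == f5 &&
          substr(seq, s + nchar(f5) + ulen,
                 s + block - 1L) == f3) {
        return(list(
          umi = substr(seq, s + nchar(f5), s + nchar(f5) + ulen - 1L),
          remainder = paste0(substr(seq, 1L, s - 1L),
                             substring(seq, s + block))
        ))
      }
    }
  }
  NULL
}

# Direct-formula Pearson correlation, independent of stats::cor.
oracle_pearson <- function(x, y) {
  xm <- x - mean(x)
  ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

random_barcodes <- function(n, len = 15L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1L))
}

# FASTQ tibble with constant quality.
fastq_tbl <- function(seqs, q = 40L, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read%04d", seq_along(seqs))
  tibble::tibble(
    read_id = ids,
    seq = seqs,
    qual = vapply(nchar(seqs), function(L) {
      intToUtf8(rep(q + 33L, L))
    }, character(1L))
  )
}

# A small simulated array + reads, shared by recovery tests.
sim_array_reads <- function(seed, m = 50L, depth = 10000L,
                            error_rate = 0.001, duplicate_rate = 0,
                            lambda = 3) {
  tpl <- barcode_template()
  lib <- sample_library(tpl, 20000L, seed = seed)
  arr <- form_array(lib, m = m, lambda = lambda, seed = seed)
  layout <- amplicon_layout(error_rate = error_rate,
                            duplicate_rate = duplicate_rate)
  gen <- generate_reads(arr, layout, depth = depth, seed = seed)
  list(array = arr, reads = gen$reads, truth = gen$truth)
}
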