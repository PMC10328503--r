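#' Read processing parameters
#'
#' Parameters for converting raw amplicon reads to deduplicated 15 bp
#' barcode observations: quality trimming/filtering, cropping, UMI
#' extraction, and barcode trimming.
#'
#' @param quality_threshold Phred cutoff for 3' quality trimming (default
#'   30); in `strict_per_base` mode, reads with any base below it are
#'   discarded instead.
#' @param max_expected_error Maximum expected number of errors per read,
#'   \eqn{\sum_i 10^{-Q_i/10}} (default 1).
#' @param crop_length Reads are cropped to this length after trimming
#'   (default 87).
#' @param umi_flank_5,umi_length,umi_flank_3 UMI block definition (defaults
#'   `CAC`, 10, `GAC`, i.e. the pattern `CAC` + 10 nt + `GAC`).
#' @param barcode_length Barcode length kept after deduplication
#'   (default 15).
#' @param nextseq_mode Treat 3'-terminal `G` bases as quality 0 during
#'   trimming (two-color chemistry emits `G` for dark cycles).
#' @param quality_filter_mode `"trim3_then_ee"` (default): 3' quality trim
#'   then expected-error filter; `"strict_per_base"`: discard reads
#'   containing any base below `quality_threshold`.
#' @param umi_flank_mismatch Allowed mismatches per UMI flank, 0 (exact,
#'   default) or 1.
#' @return A list of class `processing_params`.
#' @export
processing_params <- function(quality_threshold = 30L,
                              max_expected_error = 1.0,
                              crop_length = 87L,
                              umi_flank_5 = "CAC",
                              umi_length = 10L,
                              umi_flank_3 = "GAC",
                              barcode_length = 15L,
                              nextseq_mode = FALSE,
                              quality_filter_mode = c("trim3_then_ee",
                                                      "strict_per_base"),
                              umi_flank_mismatch = 0L) {
  quality_filter_mode <- match.arg(quality_filter_mode)
  stopifnot(quality_threshold >= 0, max_expected_error > 0,
            crop_length >= 1, barcode_length >= 1,
            umi_flank_mismatch %in% c(0L, 1L))
  structure(
    list(quality_threshold = as.integer(quality_threshold),
         max_expected_error = max_expected_error,
         crop_length = as.integer(crop_length),
         umi_flank_5 = umi_flank_5, umi_length = as.integer(umi_length),
         umi_flank_3 = umi_flank_3,
         barcode_length = as.integer(barcode_length),
         nextseq_mode = isTRUE(nextseq_mode),
         quality_filter_mode = quality_filter_mode,
         umi_flank_mismatch = as.integer(umi_flank_mismatch)),
    class = "processing_params"
  )
}

# Number of 3'-terminal bases to remove, BWA/cutadapt running-sum rule:
# over suffix lengths s, maximize sum of (threshold - q) over the suffix;
# trim the maximizing suffix if its sum is positive, else nothing.
quality_trim_length <- function(q, threshold) {
  if (length(q) == 0L) return(0L)
  s <- cumsum(threshold - rev(q))
  m <- max(s)
  if (m <= 0) 0L else which.max(s)
}

required_read_length <- function(params) {
  nchar(params$umi_flank_5) + params$umi_length +
    nchar(params$umi_flank_3) + params$barcode_length
}

#' Filter, trim and crop raw reads
#'
#' Applies the quality pipeline in this order: optional NextSeq-aware
#' (poly-G) 3' trim, 3' quality trim at `quality_threshold` using the
#' running-sum rule (or, in `strict_per_base` mode, discard of any read with
#' a base below threshold), discard of reads containing `N`, discard of
#' reads whose expected error \eqn{\sum 10^{-Q/10}} exceeds
#' `max_expected_error`, crop to `crop_length`, and discard of reads shorter
#' than the UMI-block-plus-barcode layout. A conservation tally records the
#' number of reads discarded per reason; `input == kept + sum(discarded)`.
#'
#' @param reads A FASTQ tibble from [read_fastq()] or [generate_reads()].
#' @param params A [processing_params()].
#' @return A list with `reads` (kept, trimmed and cropped tibble) and
#'   `tally` (named integer vector: `input`, `kept`, `low_quality`,
#'   `contains_N`, `expected_error`, `too_short`).
#' @export
filter_and_crop <- function(reads, params = processing_params()) {
  stopifnot(inherits(params, "processing_params"))
  n_in <- nrow(reads)
  tally <- c(input = n_in, kept = 0L, low_quality = 0L, contains_N = 0L,
             expected_error = 0L, too_short = 0L)
  if (n_in == 0L) {
    return(list(reads = reads, tally = tally))
  }
  qs <- phred_scores(reads$qual)
  thr <- params$quality_threshold

  if (params$quality_filter_mode == "strict_per_base") {
    ok <- vapply(qs, function(q) all(q >= thr), logical(1L))
    tally["low_quality"] <- sum(!ok)
    reads <- reads[ok, , drop = FALSE]
    qs <- qs[ok]
  } else {
    seq_chars <- NULL
    if (params$nextseq_mode) {
      # dark-cycle Gs: treat trailing-context G bases as quality 0
      seq_chars <- strsplit(reads$seq, "", fixed = TRUE)
    }
    trim_n <- vapply(seq_along(qs), function(i) {
      q <- qs[[i]]
      if (params$nextseq_mode) q[seq_chars[[i]] == "G"] <- 0L
      quality_trim_length(q, thr)
    }, integer(1L))
    keep_len <- nchar(reads$seq) - trim_n
    reads$seq <- substr(reads$seq, 1L, keep_len)
    reads$qual <- substr(reads$qual, 1L, keep_len)
    qs <- lapply(seq_along(qs), function(i) qs[[i]][seq_len(keep_len[i])])
  }

  has_n <- grepl("N", reads$seq, fixed = TRUE)
  tally["contains_N"] <- sum(has_n)
  reads <- reads[!has_n, , drop = FALSE]
  qs <- qs[!has_n]

  ee <- vapply(qs, function(q) sum(10^(-q / 10)), numeric(1L))
  bad_ee <- ee > params$max_expected_error
  tally["expected_error"] <- sum(bad_ee)
  reads <- reads[!bad_ee, , drop = FALSE]

  reads$seq <- substr(reads$seq, 1L, params$crop_length)
  reads$qual <- substr(reads$qual, 1L, params$crop_length)

  short <- nchar(reads$seq) < required_read_length(params)
  tally["too_short"] <- sum(short)
  reads <- reads[!short, , drop = FALSE]

  tally["kept"] <- nrow(reads)
  stopifnot(tally["input"] ==
              tally["kept"] + sum(tally[c("low_quality", "contains_N",
                                          "expected_error", "too_short")]))
  list(reads = reads, tally = tally)
}

# First occurrence of flank5 + (umi_length bases) + flank3, scanning 5'->3',
# allowing `mismatch` mismatches per flank. Returns start (1-based) or NA.
scan_umi_block <- function(seq, f5, umi_len, f3, mismatch) {
  block <- nchar(f5) + umi_len + nchar(f3)
  L <- nchar(seq)
  if (L < block) return(NA_integer_)
  f5c <- strsplit(f5, "", fixed = TRUE)[[1L]]
  f3c <- strsplit(f3, "", fixed = TRUE)[[1L]]
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (start in seq_len(L - block + 1L)) {
    mm5 <- sum(ch[start:(start + nchar(f5) - 1L)] != f5c)
    if (mm5 > mismatch) next
    p3 <- start + nchar(f5) + umi_len
    mm3 <- sum(ch[p3:(p3 + nchar(f3) - 1L)] != f3c)
    if (mm3 <= mismatch) return(start)
  }
  NA_integer_
}

#' Extract UMIs from filtered reads
#'
#' Finds the first occurrence of `umi_flank_5` + `umi_length` bases +
#' `umi_flank_3` in each read (scanning 5' to 3'), returns the internal
#' bases as the UMI and the read with the whole matched block excised
#' (prefix and suffix concatenated). Reads without a match are tallied as
#' `umi_unmatched` and dropped, not errored.
#'
#' @param reads A filtered FASTQ tibble.
#' @param params A [processing_params()].
#' @return A list with `umi_reads` (tibble: `read_id`, `umi`, `remainder`)
#'   and `tally` (`input`, `matched`, `umi_unmatched`).
#' @export
extract_umi <- function(reads, params = processing_params()) {
  stopifnot(inherits(params, "processing_params"))
  f5 <- params$umi_flank_5
  f3 <- params$umi_flank_3
  ulen <- params$umi_length
  if (params$umi_flank_mismatch == 0L) {
    pat <- paste0(f5, "[ACGTN]{", ulen, "}", f3)
    start <- regexpr(pat, reads$seq)
    start <- ifelse(start == -1L, NA_integer_, as.integer(start))
  } else {
    start <- vapply(reads$seq, scan_umi_block, integer(1L),
                    f5 = f5, umi_len = ulen, f3 = f3,
                    mismatch = params$umi_flank_mismatch, USE.NAMES = FALSE)
  }
  matched <- !is.na(start)
  block <- nchar(f5) + ulen + nchar(f3)
  s <- start[matched]
  seqs <- reads$seq[matched]
  umi <- substr(seqs, s + nchar(f5), s + nchar(f5) + ulen - 1L)
  remainder <- paste0(substr(seqs, 1L, s - 1L),
                      substring(seqs, s + block))
  list(
    umi_reads = tibble::tibble(read_id = reads$read_id[matched],
                               umi = umi, remainder = remainder),
    tally = c(input = nrow(reads), matched = sum(matched),
              umi_unmatched = sum(!matched))
  )
}

#' Deduplicate UMI-tagged reads
#'
#' Collapses reads sharing the same `(umi, remainder)` key to one
#' representative, retaining the duplicate multiplicity. Keying on the full
#' post-UMI sequence (not the UMI alone) avoids collapsing distinct barcodes
#' that collide on a UMI by chance. Idempotent: deduplicating a
#' deduplicated table changes nothing.
#'
#' @param umi_reads Tibble with columns `umi`, `remainder` (and optionally
#'   `read_id`, whose first value per key is kept as representative).
#' @return A tibble of class `dedup_table` with columns `umi`, `remainder`,
#'   `read_id` (representative), `n_reads` (duplicates per key);
#'   `sum(n_reads)` equals the number of input reads.
#' @export
deduplicate <- function(umi_reads) {
  stopifnot(all(c("umi", "remainder") %in% names(umi_reads)))
  if (!"read_id" %in% names(umi_reads)) {
    umi_reads$read_id <- as.character(seq_len(nrow(umi_reads)))
  }
  out <- umi_reads |>
    dplyr::group_by(.data$umi, .data$remainder) |>
    dplyr::summarise(read_id = dplyr::first(.data$read_id),
                     n_reads = dplyr::n(), .groups = "drop")
  class(out) <- c("dedup_table", class(out))
  out
}

#' Trim deduplicated reads to barcodes and count
#'
#' Keeps the first `barcode_length` bases of each deduplicated remainder and
#' aggregates identical barcodes, counting one per dedup key. Remainders
#' shorter than `barcode_length` are tallied `too_short` and dropped.
#'
#' @param dedup A [deduplicate()] table.
#' @param barcode_length Barcode length (default 15).
#' @return A list with `counts` (tibble `barcode`, `count`) and `tally`
#'   (`input`, `kept`, `too_short`).
#' @export
trim_to_barcode <- function(dedup, barcode_length = 15L) {
  short <- nchar(dedup$remainder) < barcode_length
  kept <- dedup[!short, , drop = FALSE]
  counts <- tibble::tibble(barcode = substr(kept$remainder, 1L,
                                            barcode_length)) |>
    dplyr::count(.data$barcode, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$barcode)
  list(counts = counts,
       tally = c(input = nrow(dedup), kept = nrow(kept),
                 too_short = sum(short)))
}

#' Demultiplex reads by sample index
#'
#' Assigns reads to samples by exact index match. The index is taken either
#' from the read header (last colon-separated field of the read id) or from
#' a 5' prefix of the configured length (which is then removed).
#'
#' @param reads A FASTQ tibble.
#' @param sample_sheet Data frame with columns `sample`, `index`; indices
#'   must be unique.
#' @param index_from `"header"` (default) or `"prefix"`.
#' @return Named list of per-sample FASTQ tibbles plus `undetermined`.
#' @export
demultiplex <- function(reads, sample_sheet,
                        index_from = c("header", "prefix")) {
  index_from <- match.arg(index_from)
  stopifnot(all(c("sample", "index") %in% names(sample_sheet)))
  if (anyDuplicated(sample_sheet$index)) {
    stop("duplicate index in sample sheet", call. = FALSE)
  }
  if (index_from == "header") {
    idx <- sub("^.*:", "", reads$read_id)
  } else {
    ilen <- unique(nchar(sample_sheet$index))
    if (length(ilen) != 1L) {
      stop("prefix demultiplexing needs equal-length indices", call. = FALSE)
    }
    idx <- substr(reads$seq, 1L, ilen)
    reads$seq <- substring(reads$seq, ilen + 1L)
    reads$qual <- substring(reads$qual, ilen + 1L)
  }
  assign <- sample_sheet$sample[match(idx, sample_sheet$index)]
  out <- lapply(stats::setNames(sample_sheet$sample, sample_sheet$sample),
                function(s) reads[which(assign == s), , drop = FALSE])
  out$undetermined <- reads[is.na(assign), , drop = FALSE]
  out
}
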