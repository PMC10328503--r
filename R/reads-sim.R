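#' Amplicon read layout
#'
#' Describes the single-end amplicon read structure used for barcode
#' quantification: an optional constant prefix, a UMI block
#' (`umi_flank_5` + random UMI + `umi_flank_3`, default `CAC` + 10 nt +
#' `GAC`), the barcode immediately after the UMI block, and a constant
#' filler suffix, cropped to `read_length` (default 87 bp).
#'
#' @param prefix Constant 5' sequence before the UMI block (default empty).
#' @param umi_flank_5,umi_flank_3 Constant flanks around the UMI.
#' @param umi_length UMI length in bases.
#' @param suffix Constant filler after the barcode; repeated as needed to
#'   reach `read_length`.
#' @param read_length Final read length in bases.
#' @param error_rate Per-base substitution probability applied i.i.d. over
#'   the whole read.
#' @param duplicate_rate Expected number of PCR duplicates per unique
#'   molecule; each molecule yields `1 + Poisson(duplicate_rate)` reads
#'   sharing one UMI.
#' @param quality_mean,quality_sd Gaussian base-quality model (Phred),
#'   truncated to `[2, 41]`.
#' @param low_quality_tail_prob Probability that a read carries a degraded
#'   3' tail (tail qualities drawn 25 Phred units lower), to exercise
#'   quality trimming.
#' @return A list of class `amplicon_layout`.
#' @export
amplicon_layout <- function(prefix = "",
                            umi_flank_5 = "CAC",
                            umi_length = 10L,
                            umi_flank_3 = "GAC",
                            suffix = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                            read_length = 87L,
                            error_rate = 0.001,
                            duplicate_rate = 0.5,
                            quality_mean = 36,
                            quality_sd = 3,
                            low_quality_tail_prob = 0) {
  stopifnot(umi_length >= 1, read_length >= 1,
            error_rate >= 0, error_rate <= 1, duplicate_rate >= 0,
            low_quality_tail_prob >= 0, low_quality_tail_prob <= 1)
  structure(
    list(prefix = prefix, umi_flank_5 = umi_flank_5,
         umi_length = as.integer(umi_length), umi_flank_3 = umi_flank_3,
         suffix = suffix, read_length = as.integer(read_length),
         error_rate = error_rate, duplicate_rate = duplicate_rate,
         quality_mean = quality_mean, quality_sd = quality_sd,
         low_quality_tail_prob = low_quality_tail_prob),
    class = "amplicon_layout"
  )
}

layout_min_length <- function(layout, barcode_length) {
  nchar(layout$prefix) + nchar(layout$umi_flank_5) + layout$umi_length +
    nchar(layout$umi_flank_3) + barcode_length
}

random_dna <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Substitute bases i.i.d. at `rate`; each error goes to one of the 3 others.
apply_substitutions <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  len <- nchar(seqs[1L])
  n_err <- rbinom(length(seqs), size = len, prob = rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample.int(len, n_err[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    for (p in pos) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

# Phred qualities as a Phred+33 string matrix flattened per read.
simulate_quality_strings <- function(n, len, layout) {
  q <- matrix(round(rnorm(n * len, layout$quality_mean, layout$quality_sd)),
              nrow = n)
  q[q < 2] <- 2
  q[q > 41] <- 41
  if (layout$low_quality_tail_prob > 0) {
    tail_reads <- which(runif(n) < layout$low_quality_tail_prob)
    for (i in tail_reads) {
      start <- sample(seq(max(2L, len - 30L), len), 1L)
      tl <- len - start + 1L
      qt <- round(rnorm(tl, layout$quality_mean - 25, layout$quality_sd))
      q[i, start:len] <- pmin(pmax(qt, 2), 41)
    }
  }
  apply(q, 1L, function(row) intToUtf8(row + 33L))
}

#' Simulate UMI-tagged amplicon reads from a pool
#'
#' Samples `depth` template molecules from the pool (with replacement,
#' proportional to frequency), tags each with a uniformly random UMI, emits
#' `1 + Poisson(duplicate_rate)` PCR-duplicate reads per molecule, applies
#' i.i.d. substitution errors at `error_rate` over the whole read, and
#' assigns Gaussian Phred qualities. Reads are
#' `prefix + flank5 + UMI + flank3 + barcode + suffix` cropped to
#' `read_length`.
#'
#' @param pool A [molecule_pool()].
#' @param layout An [amplicon_layout()].
#' @param depth Number of unique template molecules to sample (>= 1).
#' @param seed Optional integer seed (stage substream `"reads"`).
#' @param fastq_path Optional path; when given, reads are written as
#'   Phred+33 FASTQ (gzip if the path ends in `.gz`).
#' @param sidecar_path Optional path for the ground-truth sidecar TSV with
#'   columns `molecule_id`, `barcode`, `umi`, `n_reads`.
#' @return Invisibly, a list with `reads` (a FASTQ tibble: `read_id`, `seq`,
#'   `qual`) and `truth` (the sidecar tibble).
#' @export
generate_reads <- function(pool, layout = amplicon_layout(), depth,
                           seed = NULL, fastq_path = NULL,
                           sidecar_path = NULL) {
  stopifnot(inherits(pool, "molecule_pool"),
            inherits(layout, "amplicon_layout"), depth >= 1)
  bc_len <- unique(nchar(pool$barcode))
  if (length(bc_len) != 1L) {
    stop("pool barcodes must share one length", call. = FALSE)
  }
  if (layout_min_length(layout, bc_len) > layout$read_length) {
    stop("layout (", layout_min_length(layout, bc_len),
         " bases) exceeds read_length = ", layout$read_length, call. = FALSE)
  }
  out <- with_stage_seed(seed, "reads", {
    mol_barcode <- sample(pool$barcode, size = depth, replace = TRUE,
                          prob = pool_frequencies(pool))
    umi <- random_dna(depth, layout$umi_length)
    n_reads <- 1L + rpois(depth, layout$duplicate_rate)
    truth <- tibble::tibble(
      molecule_id = sprintf("M%06d", seq_len(depth)),
      barcode = mol_barcode, umi = umi, n_reads = n_reads
    )
    filler <- strrep(layout$suffix,
                     ceiling(layout$read_length / nchar(layout$suffix)))
    base_read <- substr(
      paste0(layout$prefix, layout$umi_flank_5, umi, layout$umi_flank_3,
             mol_barcode, filler),
      1L, layout$read_length
    )
    idx <- rep.int(seq_len(depth), n_reads)
    dup <- sequence(n_reads)
    seqs <- apply_substitutions(base_read[idx], layout$error_rate)
    quals <- simulate_quality_strings(length(idx), layout$read_length, layout)
    reads <- tibble::tibble(
      read_id = sprintf("%s_R%d", truth$molecule_id[idx], dup),
      seq = seqs, qual = quals
    )
    list(reads = reads, truth = truth)
  })
  if (!is.null(fastq_path)) write_fastq(out$reads, fastq_path)
  if (!is.null(sidecar_path)) {
    utils::write.table(out$truth, sidecar_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
  }
  invisible(out)
}
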