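test_that("high-quality reads are kept and cropped to 87 bp", {
  reads <- fastq_tbl(strrep("ACGT", 25), q = 40)  # 100 bases, all Q40
  out <- filter_and_crop(reads)
  expect_equal(out$tally[["kept"]], 1L)
  expect_equal(nchar(out$reads$seq), 87L)
  expect_equal(nchar(out$reads$qual), 87L)
})

test_that("reads containing N are discarded with the right reason", {
  reads <- fastq_tbl(paste0(strrep("A", 40), "N", strrep("A", 46)), q = 40)
  out <- filter_and_crop(reads)
  expect_equal(out$tally[["contains_N"]], 1L)
  expect_equal(out$tally[["kept"]], 0L)
})

test_that("a uniformly low-quality read is removed in both modes", {
  # All 87 bases at Q20 with threshold 30: the 3' running-sum trim removes
  # the entire read (every suffix scores positive), so it ends too short;
  # strict mode discards it outright as low quality.
  reads <- fastq_tbl(strrep("A", 87), q = 20)
  trim_mode <- filter_and_crop(reads, processing_params())
  expect_equal(trim_mode$tally[["too_short"]], 1L)
  expect_equal(trim_mode$tally[["kept"]], 0L)
  strict <- filter_and_crop(
    reads, processing_params(quality_filter_mode = "strict_per_base"))
  expect_equal(strict$tally[["low_quality"]], 1L)
})

test_that("expected-error filtering uses the closed form sum(10^(-Q/10))", {
  # 87 bases at Q30: EE = 87 * 0.001 = 0.087; no base is below threshold
  # so nothing is trimmed. Kept at max EE 1, discarded at max EE 0.05.
  reads <- fastq_tbl(strrep("A", 87), q = 30)
  kept <- filter_and_crop(reads, processing_params(max_expected_error = 1))
  expect_equal(kept$tally[["kept"]], 1L)
  dropped <- filter_and_crop(reads,
                             processing_params(max_expected_error = 0.05))
  expect_equal(dropped$tally[["expected_error"]], 1L)
})

test_that("3' quality trimming removes low-quality tails only", {
  good <- 60L
  tail_len <- 27L
  qual <- intToUtf8(c(rep(40L, good), rep(10L, tail_len)) + 33L)
  reads <- tibble::tibble(read_id = "r1", seq = strrep("A", 87), qual = qual)
  out <- filter_and_crop(reads, processing_params(barcode_length = 15))
  expect_equal(nchar(out$reads$seq), good)
  expect_equal(out$tally[["kept"]], 1L)
})

test_that("nextseq mode treats a trailing poly-G run as dark cycles", {
  seqs <- paste0(strrep("A", 60), strrep("G", 27))
  qual <- intToUtf8(rep(40L + 33L, 87))  # high reported quality throughout
  reads <- tibble::tibble(read_id = "r1", seq = seqs, qual = qual)
  plain <- filter_and_crop(reads, processing_params())
  expect_equal(nchar(plain$reads$seq), 87L)
  nextseq <- filter_and_crop(reads, processing_params(nextseq_mode = TRUE))
  expect_equal(nchar(nextseq$reads$seq), 60L)
})

test_that("strict and trim modes agree when every base passes threshold", {
  arr <- sim_array_reads(seed = 31, m = 10, depth = 300, error_rate = 0)
  qs <- phred_scores(arr$reads$qual)
  all_good <- vapply(qs, function(q) all(q >= 30), logical(1))
  reads <- arr$reads[all_good, ]
  a <- filter_and_crop(reads, processing_params())
  b <- filter_and_crop(reads,
                       processing_params(quality_filter_mode =
                                           "strict_per_base"))
  expect_equal(a$reads, b$reads)
  expect_equal(a$tally[["kept"]], b$tally[["kept"]])
})

test_that("filtering conserves reads across discard reasons", {
  arr <- sim_array_reads(seed = 32, m = 30, depth = 3000,
                         error_rate = 0.002, duplicate_rate = 0.5)
  # inject some pathological reads
  reads <- dplyr::bind_rows(
    arr$reads,
    fastq_tbl(strrep("N", 87), q = 35, ids = "bad_n"),
    fastq_tbl(strrep("A", 20), q = 35, ids = "short"),
    fastq_tbl(strrep("A", 87), q = 12, ids = "lowq")
  )
  out <- filter_and_crop(reads)
  expect_equal(
    out$tally[["input"]],
    out$tally[["kept"]] + out$tally[["contains_N"]] +
      out$tally[["expected_error"]] + out$tally[["too_short"]] +
      out$tally[["low_quality"]]
  )
  expect_equal(out$tally[["input"]], nrow(reads))
})

test_that("UMI extraction matches the documented examples", {
  p <- processing_params()
  r1 <- extract_umi(fastq_tbl("CACAAAAAAAAAAGACTTTTT"), p)
  expect_equal(r1$umi_reads$umi, "AAAAAAAAAA")
  expect_equal(r1$umi_reads$remainder, "TTTTT")

  r2 <- extract_umi(fastq_tbl("CATAAAAAAAAAAGACTTTTT"), p)  # flank mismatch
  expect_equal(nrow(r2$umi_reads), 0L)
  expect_equal(r2$tally[["umi_unmatched"]], 1L)

  r3 <- extract_umi(fastq_tbl("GGCACGGGGGGGGGGGACTTT"), p)
  expect_equal(r3$umi_reads$umi, "GGGGGGGGGG")
  expect_equal(r3$umi_reads$remainder, "GGTTT")
})

test_that("UMI extraction agrees with a plain scanning oracle", {
  set.seed(41)
  seqs <- c(
    replicate(150, paste0(
      paste(sample(c("A", "C", "G", "T"), sample(0:6, 1), replace = TRUE),
            collapse = ""),
      "CAC", paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
                   collapse = ""),
      "GAC", paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                   collapse = ""))),
    random_barcodes(50, len = 40)   # mostly unmatched
  )
  got <- extract_umi(fastq_tbl(seqs), processing_params())
  expected <- lapply(seqs, oracle_umi)
  matched <- !vapply(expected, is.null, logical(1))
  expect_equal(got$tally[["matched"]], sum(matched))
  expect_equal(got$umi_reads$umi,
               vapply(expected[matched], `[[`, character(1), "umi"))
  expect_equal(got$umi_reads$remainder,
               vapply(expected[matched], `[[`, character(1), "remainder"))
})

test_that("one flank mismatch is tolerated only when configured", {
  read <- fastq_tbl("CATAAAAAAAAAAGACTTTTT")
  strict <- extract_umi(read, processing_params())
  expect_equal(nrow(strict$umi_reads), 0L)
  loose <- extract_umi(read, processing_params(umi_flank_mismatch = 1L))
  expect_equal(loose$umi_reads$umi, "AAAAAAAAAA")
})

test_that("deduplication keys on (UMI, remainder) and is idempotent", {
  x <- tibble::tibble(
    read_id = paste0("r", 1:5),
    umi = c("AAAA", "AAAA", "AAAA", "AAAA", "CCCC"),
    remainder = c("TTT", "TTT", "TTT", "GGG", "TTT")
  )
  dd <- deduplicate(x)
  expect_equal(nrow(dd), 3L)
  expect_equal(sum(dd$n_reads), 5L)
  expect_equal(dd$n_reads[dd$umi == "AAAA" & dd$remainder == "TTT"], 3L)
  # same UMI, different remainder stays distinct
  expect_equal(sum(dd$umi == "AAAA"), 2L)

  again <- deduplicate(dd[, c("read_id", "umi", "remainder")])
  expect_equal(nrow(again), nrow(dd))
  expect_true(all(again$n_reads == 1L))

  empty <- deduplicate(tibble::tibble(umi = character(),
                                      remainder = character()))
  expect_equal(nrow(empty), 0L)
})

test_that("deduplication is order-invariant", {
  set.seed(8)
  x <- tibble::tibble(
    read_id = paste0("r", 1:200),
    umi = sample(random_barcodes(20, 10), 200, replace = TRUE),
    remainder = sample(random_barcodes(10, 15), 200, replace = TRUE)
  )
  a <- deduplicate(x)
  b <- deduplicate(x[sample(nrow(x)), ])
  key <- function(t) t[order(t$umi, t$remainder), c("umi", "remainder",
                                                    "n_reads")]
  expect_equal(key(a), key(b))
})

test_that("barcode trimming keeps 15 bases and aggregates dedup keys", {
  dd <- deduplicate(tibble::tibble(
    read_id = paste0("r", 1:4),
    umi = c("A", "C", "G", "T"),
    remainder = c("ACGTACGTACGTACGTTTT",   # -> ACGTACGTACGTACG
                  "ACGTACGTACGTACGAAAA",   # same first 15
                  "TTTTTTTTTT",            # too short
                  "GGGGGGGGGGGGGGG")
  ))
  out <- trim_to_barcode(dd, 15L)
  expect_equal(out$tally[["too_short"]], 1L)
  expect_equal(sum(out$counts$count), 3)
  expect_equal(out$counts$count[out$counts$barcode == "ACGTACGTACGTACG"], 2)
})

test_that("noise-free simulator reads recover sidecar barcodes exactly", {
  arr <- sim_array_reads(seed = 33, m = 25, depth = 2000, error_rate = 0,
                         duplicate_rate = 0)
  filt <- filter_and_crop(arr$reads)
  umi <- extract_umi(filt$reads)
  dd <- deduplicate(umi$umi_reads)
  out <- trim_to_barcode(dd)
  expect_setequal(out$counts$barcode, arr$array$barcode)
  # with no duplicates and no errors every read maps to its true barcode
  truth <- arr$truth[match(sub("_R\\d+$", "", umi$umi_reads$read_id),
                           arr$truth$molecule_id), ]
  expect_identical(substr(umi$umi_reads$remainder, 1, 15), truth$barcode)
  expect_identical(umi$umi_reads$umi, truth$umi)
})

test_that("demultiplexing partitions reads exactly by index", {
  sheet <- data.frame(sample = c("s1", "s2"), index = c("ACGT", "TGCA"))
  reads <- fastq_tbl(rep(strrep("A", 20), 6),
                     ids = c("r1:ACGT", "r2:TGCA", "r3:ACGT", "r4:GGGG",
                             "r5:TGCA", "r6:ACGT"))
  out <- demultiplex(reads, sheet, index_from = "header")
  expect_equal(nrow(out$s1), 3L)
  expect_equal(nrow(out$s2), 2L)
  expect_equal(nrow(out$undetermined), 1L)
  expect_equal(nrow(out$s1) + nrow(out$s2) + nrow(out$undetermined),
               nrow(reads))

  expect_error(
    demultiplex(reads, data.frame(sample = c("a", "b"),
                                  index = c("ACGT", "ACGT"))),
    "duplicate index"
  )
})

test_that("prefix demultiplexing strips the index from the read", {
  sheet <- data.frame(sample = "s1", index = "ACGT")
  reads <- fastq_tbl("ACGTTTTTT")
  out <- demultiplex(reads, sheet, index_from = "prefix")
  expect_equal(out$s1$seq, "TTTTT")
  expect_equal(nchar(out$s1$qual), 5L)
})
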