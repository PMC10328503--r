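test_that("library sampling respects the template and conserves molecules", {
  tpl <- barcode_template("ACGT")
  pool <- sample_library(tpl, 100, seed = 1)
  expect_equal(nrow(pool), 1L)
  expect_equal(pool$barcode, "ACGT")
  expect_equal(pool$count, 100)

  pool1 <- sample_library(barcode_template(), 1, seed = 1)
  expect_equal(nrow(pool1), 1L)
  expect_equal(pool1$count, 1)

  tpl15 <- barcode_template()
  pool2 <- sample_library(tpl15, 5000, seed = 7)
  expect_equal(sum(pool2$count), 5000)
  expect_true(all(nchar(pool2$barcode) == 15L))
  expect_true(all(substr(pool2$barcode, 4, 4) == "C"))
  expect_true(all(substr(pool2$barcode, 11, 11) == "A"))
})

test_that("library occupancy matches the classical occupancy formula", {
  tpl <- barcode_template("NNNNNN")  # space 4096
  S <- enumerate_space(tpl)
  n <- 4096
  expected <- S * (1 - (1 - 1 / S)^n)   # ~ S (1 - e^-1) = 2589.6
  distinct <- vapply(1:5, function(s) {
    nrow(sample_library(tpl, n, seed = s))
  }, numeric(1))
  # sd of occupancy is ~ sqrt(S e^-1 (1 - e^-1)) ~ 31; allow 4 sd per draw
  expect_true(all(abs(distinct - expected) < 125))
})

test_that("library sampling is seed-deterministic", {
  tpl <- barcode_template()
  a <- sample_library(tpl, 2000, seed = 42)
  b <- sample_library(tpl, 2000, seed = 42)
  expect_identical(a$barcode, b$barcode)
  expect_identical(a$count, b$count)
})

test_that("deterministic PCR efficiency preserves proportions exactly", {
  pool <- molecule_pool(c("AAAA", "CCCC", "GGGG"), c(5, 3, 2))
  out <- simulate_pcr(pool, cycles = 7, efficiency = 1, seed = 1)
  expect_equal(pool_frequencies(out), pool_frequencies(pool))
  expect_equal(out$count, pool$count * 2^7)
})

test_that("closed-form doubling: e = (1, 0) over 3 cycles gives 8/9, 1/9", {
  pool <- molecule_pool(c("AAAA", "TTTT"), c(1, 1))
  out <- simulate_pcr(pool, cycles = 3, efficiency = c(1, 0), seed = 1)
  expect_equal(pool_frequencies(out), c(8 / 9, 1 / 9))
})

test_that("negative cycle counts are rejected", {
  pool <- molecule_pool("AAAA", 1)
  expect_error(simulate_pcr(pool, cycles = -1), "cycles")
})

test_that("higher Beta efficiency variance concentrates more read mass", {
  tpl <- barcode_template()
  lib <- sample_library(tpl, 10000, seed = 3)
  top_share <- function(pool, frac = 0.01) {
    f <- sort(pool_frequencies(pool), decreasing = TRUE)
    sum(f[seq_len(ceiling(frac * length(f)))])
  }
  wide <- simulate_pcr(lib, cycles = 10, efficiency_beta = c(2, 2), seed = 5)
  narrow <- simulate_pcr(lib, cycles = 10, efficiency_beta = c(2000, 2000),
                         seed = 5)
  expect_gt(top_share(wide), top_share(narrow))
})

test_that("array formation collapses to uniform copies as lambda -> 0", {
  tpl <- barcode_template()
  lib <- sample_library(tpl, 5000, seed = 2)
  arr <- form_array(lib, m = 40, lambda = 1e-14, jackpot_prob = 0, seed = 2)
  expect_equal(nrow(arr), 40L)
  expect_true(all(arr$count == 1))
  expect_equal(pool_frequencies(arr), rep(1 / 40, 40))
})

test_that("requesting more founders than barcodes errors", {
  pool <- molecule_pool(c("AA", "CC"), c(1, 1))
  expect_error(form_array(pool, m = 3, lambda = 1), "exceeds")
})

test_that("array copy numbers pass a zero-truncated Poisson GOF", {
  tpl <- barcode_template()
  lib <- sample_library(tpl, 20000, seed = 11)
  pass <- vapply(1:100, function(s) {
    arr <- form_array(lib, m = 91, lambda = 3, jackpot_prob = 0, seed = s)
    fit <- fit_zt_poisson(arr$count)
    isTRUE(fit$p_value > 0.01)
  }, logical(1))
  expect_gte(sum(pass), 95)
})

test_that("frequency CV is no larger for high-diversity arrays", {
  # Under exchangeable ZT-Poisson copies the frequency CV has the same
  # expectation at any m, so equality-within-noise is the honest bound.
  tpl <- barcode_template()
  lib <- sample_library(tpl, 30000, seed = 4)
  cvs <- vapply(1:20, function(s) {
    cv <- function(m) {
      arr <- form_array(lib, m = m, lambda = 3, jackpot_prob = 0.05,
                        jackpot_factor_log_sd = 1, seed = s)
      f <- pool_frequencies(arr)
      sd(f) / mean(f)
    }
    c(big = cv(3001L), small = cv(91L))
  }, numeric(2))
  expect_lte(mean(cvs["big", ]), mean(cvs["small", ]) + 0.2)
})

test_that("integrant draws are multinomial with optional bias", {
  single <- molecule_pool("AAAA", 3, stage = "array")
  out <- draw_integrants(single, 500, seed = 1)
  expect_equal(out$barcode, "AAAA")
  expect_equal(out$count, 500)

  # large-n convergence of integrant frequencies to array frequencies
  arr <- molecule_pool(c("AAAA", "CCCC", "GGGG", "TTTT"), c(4, 3, 2, 1),
                       stage = "array")
  big <- draw_integrants(arr, 1e6, seed = 2)
  f <- pool_frequencies(arr)
  sd_max <- max(sqrt(f * (1 - f) / 1e6))
  expect_lt(max(abs(big$count[match(arr$barcode, big$barcode)] / 1e6 - f)),
            3 * sd_max)

  # bias 2 on one of two 50/50 barcodes -> expected share 2/3
  half <- molecule_pool(c("AAAA", "TTTT"), c(1, 1), stage = "array")
  n <- 20000
  biased <- draw_integrants(half, n, bias = c(AAAA = 2), seed = 3)
  share <- biased$count[biased$barcode == "AAAA"] / n
  expect_lt(abs(share - 2 / 3), 3 * sqrt((2 / 3) * (1 / 3) / n))

  expect_error(draw_integrants(half, 10, bias = c(AAAA = -1)), "negative")
  expect_equal(sum(draw_integrants(half, 777, seed = 4)$count), 777)
})

test_that("noise-free reads carry UMI and barcode at fixed offsets", {
  arr <- sim_array_reads(seed = 9, m = 20, depth = 500, error_rate = 0,
                         duplicate_rate = 0)
  expect_equal(nrow(arr$reads), 500L)
  expect_equal(nrow(arr$truth), 500L)
  expect_identical(substr(arr$reads$seq, 4, 13), arr$truth$umi)
  expect_identical(substr(arr$reads$seq, 17, 31), arr$truth$barcode)
  expect_true(all(substr(arr$reads$seq, 1, 3) == "CAC"))
  expect_true(all(substr(arr$reads$seq, 14, 16) == "GAC"))
  expect_true(all(nchar(arr$reads$seq) == 87L))
})

test_that("substitution errors hit barcodes at the closed-form rate", {
  arr <- sim_array_reads(seed = 10, m = 20, depth = 20000,
                         error_rate = 0.001, duplicate_rate = 0)
  obs_bc <- substr(arr$reads$seq, 17, 31)
  frac <- mean(obs_bc != arr$truth$barcode)
  expected <- 1 - (1 - 0.001)^15     # ~ 0.0149
  expect_lt(abs(frac - expected),
            4 * sqrt(expected * (1 - expected) / 20000))
})

test_that("duplicate rate 1 gives about two reads per molecule", {
  arr <- sim_array_reads(seed = 12, m = 20, depth = 5000, error_rate = 0,
                         duplicate_rate = 1)
  expect_equal(sum(arr$truth$n_reads), nrow(arr$reads))
  expect_lt(abs(mean(arr$truth$n_reads) - 2), 0.06)
})

test_that("read generation is byte-identical under a fixed seed", {
  tpl <- barcode_template()
  lib <- sample_library(tpl, 2000, seed = 5)
  arr <- form_array(lib, m = 10, lambda = 2, seed = 5)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.fastq"); f2 <- file.path(d, "b.fastq")
  s1 <- file.path(d, "a.tsv"); s2 <- file.path(d, "b.tsv")
  generate_reads(arr, amplicon_layout(), depth = 300, seed = 99,
                 fastq_path = f1, sidecar_path = s1)
  generate_reads(arr, amplicon_layout(), depth = 300, seed = 99,
                 fastq_path = f2, sidecar_path = s2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(readLines(s1), readLines(s2))
})

test_that("layouts longer than the read are rejected", {
  pool <- molecule_pool(strrep("A", 15), 5)
  expect_error(
    generate_reads(pool, amplicon_layout(read_length = 20), depth = 10),
    "read_length"
  )
})
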