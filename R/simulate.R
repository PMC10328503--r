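#' Sample a synthesized oligo library
#'
#' Draws `n_molecules` molecules uniformly at random from the template space
#' (fixed positions respected, free positions i.i.d. over A/C/G/T) and
#' returns their abundances. This emulates synthesis of a degenerate oligo
#' library: with \eqn{n} draws from a space of size \eqn{S}, the expected
#' number of distinct sequences is \eqn{S(1 - (1 - 1/S)^n)}, the classical
#' occupancy formula.
#'
#' @param template A [barcode_template()].
#' @param n_molecules Number of molecules to draw (>= 1).
#' @param seed Optional integer seed (stage substream `"library"`).
#' @return A [molecule_pool()] with stage `"library"`; integer counts summing
#'   to `n_molecules`.
#' @export
sample_library <- function(template, n_molecules, seed = NULL) {
  stopifnot(inherits(template, "barcode_template"),
            n_molecules >= 1)
  n_molecules <- as.numeric(n_molecules)
  space <- enumerate_space(template)
  with_stage_seed(seed, "library", {
    # sample indices in [1, 4^k]; exact for spaces up to 2^53
    idx <- floor(runif(n_molecules) * space) + 1
    tab <- table(idx)
    seqs <- barcode_from_index(template, as.numeric(names(tab)))
    molecule_pool(seqs, as.numeric(tab), stage = "library")
  })
}

# One binomial duplication round; exact unless counts are so large that
# rbinom's integer return would overflow, then a normal approximation.
grow_once <- function(count, eff) {
  big <- count > 1e9
  out <- count
  if (any(!big)) {
    out[!big] <- count[!big] + rbinom(sum(!big), size = count[!big],
                                      prob = eff[!big])
  }
  if (any(big)) {
    mu <- count[big] * eff[big]
    sdv <- sqrt(count[big] * eff[big] * (1 - eff[big]))
    out[big] <- count[big] + pmax(0, round(rnorm(sum(big), mu, sdv)))
  }
  out
}

#' Simulate PCR amplification with per-template efficiency
#'
#' Each barcode is assigned an amplification efficiency and undergoes
#' `cycles` rounds of binomial duplication: a molecule duplicates in a cycle
#' with probability equal to its efficiency. Heterogeneous efficiencies
#' compound over cycles and produce "jackpotting" — a minority of sequences
#' overrepresented relative to expectation. With a common efficiency of 1
#' every abundance exactly doubles each cycle, so frequencies are preserved.
#'
#' @param pool A [molecule_pool()].
#' @param cycles Number of PCR cycles (>= 0).
#' @param efficiency Either `NULL` (draw per-barcode efficiencies from
#'   `Beta(efficiency_beta[1], efficiency_beta[2])`) or a numeric vector of
#'   per-barcode duplication probabilities in `[0, 1]` (length 1 or
#'   `nrow(pool)`) used instead of Beta draws. Efficiencies of exactly 0 or
#'   1 make each cycle deterministic (no duplication / exact doubling).
#' @param efficiency_beta Length-2 shape vector `(a, b)` of the Beta
#'   efficiency distribution. Default `c(20, 5)` (mean 0.8) gives a modest
#'   efficiency spread and a small jackpot tail at realistic depths.
#' @param seed Optional integer seed (stage substream `"pcr"`).
#' @return A [molecule_pool()] with stage `"injection_mix"`. Barcodes whose
#'   lineage dies out entirely (efficiency 0 is impossible to die with —
#'   counts never decrease) are retained.
#' @export
simulate_pcr <- function(pool, cycles = 10L, efficiency = NULL,
                         efficiency_beta = c(20, 5), seed = NULL) {
  stopifnot(inherits(pool, "molecule_pool"))
  if (cycles < 0) stop("cycles must be >= 0", call. = FALSE)
  n <- nrow(pool)
  with_stage_seed(seed, "pcr", {
    if (is.null(efficiency)) {
      stopifnot(length(efficiency_beta) == 2L, all(efficiency_beta > 0))
      eff <- stats::rbeta(n, efficiency_beta[1L], efficiency_beta[2L])
    } else {
      stopifnot(all(efficiency >= 0), all(efficiency <= 1))
      eff <- rep_len(efficiency, n)
    }
    count <- pool$count
    deterministic <- all(eff %in% c(0, 1))
    for (cyc in seq_len(cycles)) {
      if (deterministic) {
        count <- count * (1 + eff)
      } else {
        count <- grow_once(count, eff)
      }
    }
    molecule_pool(pool$barcode, count, stage = "injection_mix")
  })
}

# Zero-truncated Poisson sampler by inverse CDF: u uniform on (P(X=0), 1].
rztpois <- function(n, lambda) {
  stopifnot(lambda >= 0)
  if (lambda < 1e-12) return(rep(1L, n))
  p0 <- exp(-lambda)
  qpois(p0 + runif(n) * (1 - p0), lambda)
}

#' Form an extrachromosomal array from an injection mix
#'
#' Array formation is modeled as founder sampling with copy-number
#' amplification: `m` distinct founder barcodes are drawn without replacement
#' with probability proportional to their injection-mix frequency; each
#' founder receives a copy number drawn from a zero-truncated Poisson with
#' mean parameter `lambda`; and, independently with probability
#' `jackpot_prob`, a founder's copy number is multiplied by a log-normal
#' factor `exp(Normal(0, jackpot_factor_log_sd))` (rounded up), representing
#' sporadic early amplification during array assembly.
#'
#' @param pool A [molecule_pool()] (typically stage `"injection_mix"`).
#' @param m Number of founder barcodes (>= 1, <= number of distinct barcodes).
#' @param lambda Zero-truncated Poisson rate for copy numbers (> 0; as
#'   `lambda -> 0` all copy numbers are 1).
#' @param jackpot_prob Per-founder probability of a jackpot amplification.
#' @param jackpot_factor_log_sd Log-scale s.d. of the jackpot factor.
#' @param seed Optional integer seed (stage substream `"array"`).
#' @return A [molecule_pool()] with stage `"array"` and exactly `m` barcodes.
#' @export
form_array <- function(pool, m, lambda = 3, jackpot_prob = 0,
                       jackpot_factor_log_sd = 1, seed = NULL) {
  stopifnot(inherits(pool, "molecule_pool"), m >= 1,
            jackpot_prob >= 0, jackpot_prob <= 1,
            jackpot_factor_log_sd > 0, lambda >= 0)
  if (m > nrow(pool)) {
    stop("m = ", m, " exceeds the ", nrow(pool),
         " distinct barcodes available", call. = FALSE)
  }
  with_stage_seed(seed, "array", {
    founders <- sample(pool$barcode, size = m, replace = FALSE,
                       prob = pool_frequencies(pool))
    copies <- as.numeric(rztpois(m, lambda))
    hit <- runif(m) < jackpot_prob
    if (any(hit)) {
      copies[hit] <- ceiling(copies[hit] *
                               exp(rnorm(sum(hit), 0, jackpot_factor_log_sd)))
    }
    molecule_pool(founders, copies, stage = "array")
  })
}

#' Draw genomic integrants from an array
#'
#' Integration of single barcodes from the array into the genomic landing
#' pad is modeled as multinomial sampling: integrant counts are
#' `Multinomial(n_integrants, p)` with \eqn{p_i \propto f_i b_i}, where
#' \eqn{f_i} is the array frequency and \eqn{b_i} an optional per-barcode
#' integration bias (default 1).
#'
#' @param array A [molecule_pool()] with stage `"array"` (any pool works).
#' @param n_integrants Number of integrants to draw (>= 1).
#' @param bias Optional named numeric vector of positive multipliers; names
#'   are barcodes, unnamed barcodes get bias 1.
#' @param seed Optional integer seed (stage substream `"integrants"`).
#' @return A [molecule_pool()] with stage `"integrants"`; integer counts
#'   summing to `n_integrants` (barcodes drawn zero times are dropped).
#' @export
draw_integrants <- function(array, n_integrants, bias = NULL, seed = NULL) {
  stopifnot(inherits(array, "molecule_pool"), n_integrants >= 1)
  b <- rep(1, nrow(array))
  if (!is.null(bias)) {
    stopifnot(is.numeric(bias), !is.null(names(bias)))
    if (any(bias < 0)) stop("negative integration bias", call. = FALSE)
    hit <- match(names(bias), array$barcode)
    if (anyNA(hit)) stop("bias names not in array", call. = FALSE)
    b[hit] <- bias
  }
  p <- pool_frequencies(array) * b
  p <- p / sum(p)
  with_stage_seed(seed, "integrants", {
    counts <- as.numeric(rmultinom(1L, size = n_integrants, prob = p))
    keep <- counts > 0
    molecule_pool(array$barcode[keep], counts[keep], stage = "integrants")
  })
}
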