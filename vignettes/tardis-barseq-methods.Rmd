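---
title: "Models and methods behind tardisbarseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tardisbarseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tardisbarseq)
```

# Overview

`tardisbarseq` quantifies barcode amplicon sequencing of TARDIS
(Transgenic Arrays Resulting in Diversity of Integrated Sequences)
libraries: synthetic 15 bp barcodes carried on *C. elegans*
extrachromosomal arrays and integrated singly into a genomic landing pad.
The package has two halves that validate each other: a generative
simulator of the library → injection mix → array → integrant → read
process, and the analysis chain (read processing, clustering, statistics)
that recovers the simulated quantities. This vignette documents the
models, the defaults and their rationale, the numerical choices, and the
places where the design was genuinely open.

# The generative model

## Barcode space

A barcode template is a pattern over `{A,C,G,T,N}`; `N` marks a free
position. The default `NNNCNNTNTNANNNN` has 11 free positions (space
$4^{11} = 4{,}194{,}304$) and four fixed bases — C, T, T, A at positions
4, 7, 9, 11 (1-based). Fixed bases give the analysis an internal QC
signal: in clean data the position probability matrix must put mass 1 on
them. Coordinates throughout the package are 1-based and inclusive, the R
convention.

## Library synthesis and PCR jackpotting

`sample_library()` draws molecules uniformly over the template space,
emulating a synthesized degenerate oligo pool. With $n$ draws from a
space of size $S$, the expected number of distinct barcodes is the
occupancy value $S(1-(1-1/S)^n)$; tests check the simulator against this
closed form on a small space.

`simulate_pcr()` models amplification skew mechanistically: each barcode
$i$ receives an efficiency $e_i \sim \mathrm{Beta}(a, b)$ held fixed
across cycles, and each of `cycles` rounds duplicates every molecule
independently with probability $e_i$ (binomial growth,
$n_{t+1} = n_t + \mathrm{Bin}(n_t, e_i)$). Efficiency heterogeneity
compounds geometrically and yields "jackpotting" — a small minority of
sequences with far more than their share of reads — which is the simplest
mechanism consistent with observing jackpots after few cycles among
physically identical templates. The default shape is
$\mathrm{Beta}(20, 5)$ (mean 0.8): a realistic per-template efficiency
spread that produces a sub-percent jackpot tail at the simulated depths.
With a degenerate efficiency (all $e_i$ equal to 1) every abundance
exactly doubles per cycle, so frequencies are preserved — a property the
tests assert exactly. Counts switch to a Gaussian approximation of the
binomial only above $10^9$ molecules per barcode (integer overflow
territory); at the scales used anywhere in this package the exact path is
taken.

## Array formation

`form_array()` treats array assembly as founder sampling with copy-number
amplification:

* `m` distinct founders sampled without replacement, probability
  proportional to injection-mix frequency. `m` is a free parameter
  (observed arrays span roughly 90–3000 unique barcodes); the biology
  selecting `m` is not modeled.
* Each founder receives a copy number from a zero-truncated Poisson
  (ZTP) with rate `lambda` (default 3). ZTP is the natural "at least one
  copy, Poisson-like replication" model, and the observed within-array
  frequency distributions are Poisson-shaped. As `lambda` $\to 0$ all
  copy numbers collapse to 1.
* Independently with probability `jackpot_prob`, a founder's copy number
  is multiplied by $e^{Z}$, $Z \sim N(0, \sigma)$, rounded up. The
  amplification process early in array formation is unknown, so a
  log-normal multiplicative factor was chosen as the least-structured
  positive heavy-tailed form; it is off (`jackpot_prob = 0`) by default.

One consequence worth stating: with exchangeable ZTP copies, the
coefficient of variation of array frequencies equals the CV of the copy
numbers and is therefore *independent of `m` in expectation*. The
observed pattern "more diverse arrays have more even frequencies" is thus
reproduced only as equality-within-noise by this model, and the
corresponding test asserts the CV for `m = 3001` is no larger than for
`m = 91` up to sampling error, not strictly smaller.

## Integration and reads

`draw_integrants()` draws $\mathrm{Multinomial}(n, p)$ counts with
$p_i \propto f_i b_i$ — frequency-proportional integration with an
optional per-barcode bias $b_i$ used to plant over- and under-integrating
outliers.

`generate_reads()` samples `depth` template molecules (with replacement,
by frequency), tags each with a uniform 10 nt UMI, emits
$1 + \mathrm{Pois}(\texttt{duplicate\_rate})$ PCR-duplicate reads per
molecule, and writes 87 bp Phred+33 FASTQ plus a ground-truth sidecar.
The default read layout is `CAC` + UMI(10) + `GAC` + barcode(15) +
constant filler, cropped to 87 bp — i.e. the UMI block is 5′-anchored and
the barcode is the first 15 bases that survive UMI excision, consistent
with a processing chain that trims deduplicated reads to 15 bp from the
5′ end. The full amplicon structure is configurable because only the UMI
pattern and the final lengths are fixed by the assay. Errors are i.i.d.
substitutions over the whole read (default $10^{-3}$); indels are not
simulated by default, though the Levenshtein clustering downstream would
absorb them. Qualities are Gaussian (mean 36, sd 3), truncated to
[2, 41], with an optional low-quality 3′ tail
(`low_quality_tail_prob`) to exercise trimming.

All stages draw from per-stage substreams derived deterministically from
one top-level seed, so each stage is individually reproducible and
re-running a configuration is byte-identical.

# Read processing

`filter_and_crop()` applies, in order: optional NextSeq-aware trimming
(two-color chemistry reports dark cycles as high-confidence `G`, so
3′-context `G` bases are treated as quality 0), 3′ quality trimming at
Q30 by the running-sum rule (trim the suffix maximizing
$\sum (\mathrm{threshold} - Q_i)$ when positive — the standard
quality-trimmer algorithm), removal of reads containing `N`, removal of
reads with expected errors $\sum 10^{-Q/10}$ above 1, cropping to 87 bp,
and removal of reads shorter than the UMI-block-plus-barcode layout
(31 bp by default). The stage order — trim, then filter, then crop — was
chosen so the expected-error filter sees only bases that survive
trimming. Note one sharp edge of the trimming semantics: a read whose
*every* base is below threshold is trimmed away entirely and ends in the
`too_short` tally; a strict per-base discard mode
(`quality_filter_mode = "strict_per_base"`) is provided for the literal
"discard reads with any base < Q30" reading, and the two modes agree on
reads whose bases all pass the threshold.

UMI extraction searches for the first occurrence of
`CAC` + 10 bases + `GAC` scanning 5′→3′ (search, not anchor, so indels or
demultiplexing remnants upstream of the block do not lose the read);
flank mismatch tolerance defaults to 0, with 1 available. Deduplication
keys on the pair (UMI, full post-UMI remainder), not the UMI alone: with
$n$ molecules and $4^{10}$ UMIs, chance UMI collisions between different
barcodes occur at rate $\approx n/4^{10}$ and must not collapse distinct
barcodes. Reads failing the template's fixed bases are *not* filtered —
the length rule after clustering is the only sequence-composition filter
— but fixed-base conformity is visible in the logo matrix as QC.

Every stage returns a conservation tally (input = kept + per-reason
discards), checked by the tests and echoed in the run summary.

# Barcode error correction

`cluster_barcodes()` implements abundance-greedy sphere clustering:
sequences in decreasing count order (ties lexicographic) join the nearest
centroid within Levenshtein radius `r` whose own input count is at least
`merge_ratio` times theirs, else found a new centroid. Defaults `r = 2`
(two sequencing errors on a 15-mer at $\varepsilon \approx 10^{-3}$ are
already rare; radius 2 also catches one error plus one indel) and
`merge_ratio = 5` (the conventional sphere-clustering ratio). Ambiguities
are resolved deterministically: nearest distance, then highest centroid
count, then lexicographic order. The merge gate compares against the
centroid's *own input count*, not its running aggregated mass, which
makes the rule order-stable and matches standard sphere clustering.
Centroids whose length differs from 15 are dropped *after* clustering, so
indel-bearing reads can still be rescued into a 15-mer centroid before
the length rule applies.

The Levenshtein kernel is a banded dynamic program in C++ with an early
exit at a distance cap, since clustering only ever needs distances up to
`r`; `utils::adist` serves as the independent oracle in the tests, and a
brute-force reimplementation of the greedy rule over the full distance
matrix is checked against the production path on hundreds of random
instances.

# Statistics

**Threshold.** The plateau rule formalizes "choose the cutoff where the
unique-barcode count stabilizes": with $u(c)$ the number of barcodes at
count $\ge c$, the threshold is the smallest $c$ with
$(u(c)-u(c+k))/u(c) < 1\%$ for window $k = 3$. If no plateau exists below
the 99th percentile of counts, the conservative fallback 5 is returned
with a warning flag, so the historical fixed threshold remains exactly
reproducible.

**Jackpots.** Barcodes with raw counts strictly above 50 (an
injection-mix convention; arrays are only analyzed this way on request),
reported with their read-mass and unique-barcode fractions.

**Logos.** `position_probabilities()` returns a 4 × L column-stochastic
matrix; default weighting counts each barcode once (`unique`), since
per-barcode probabilities are what a library-composition logo shows;
`read_weighted` is available for abundance-weighted views.

**ZTP fit.** The MLE solves $\lambda/(1-e^{-\lambda}) = \bar{x}$ by
safeguarded Newton iteration (bisection bracket, tolerance $10^{-10}$).
Sample means $\le 1$ put the MLE on the $\lambda \to 0$ boundary, which
is reported as such with no GOF. The χ² GOF merges right-tail bins until
every expected count is ≥ 5 and uses bins − 2 degrees of freedom.

**Correlation.** Pearson r between array frequencies and integrant
frequencies, per replicate and pooled by concatenating all replicates'
points (the single-R-over-all-replicates reading of a multi-replicate
scatter); the mean per-replicate r is also reported since either
convention is defensible. The default universe is the union of barcode
sets with zero fill — observed arrays and F1 sets differ (e.g. 91 vs 118
barcodes at a 5-read threshold), and the union view penalizes
disagreement on membership; `intersection` is available. p-values use
$t = r\sqrt{(n-2)/(1-r^2)}$ with the Student-t tail evaluated in log
space, so values of order $10^{-150}$ survive as finite `log10_p`.

**Replicated outliers.** Per replicate, ordinary least squares of
integrant on array frequency, then *sequential deletion*: flag the
largest externally studentized residual above $z = 3$, refit without
flagged points, repeat (flagging at most 20% of points). Single-pass
studentized residuals suffer masking — one gross outlier inflates the
residual scale and hides a smaller one — and in simulations with a ×4
and a ×0.25 planted bias the single-pass rule recovered both in fewer
than half of runs, while peeling recovers exactly the planted pair
essentially always. A barcode is a replicated outlier when flagged in at
least 3 replicates, labeled over-/under-integrating by the sign of its
mean residual from the outlier-free fits. All three knobs
(`outlier_z`, `outlier_min_replicates`, the peel cap) are parameters.

No multiple-testing correction is applied anywhere; p-values are
reported, never used for gating.

# What the simulator does and does not emulate

It emulates the statistical structure the analysis relies on: uniform
degenerate synthesis, PCR efficiency heterogeneity (jackpotting), founder
sampling with ZTP copy numbers and optional log-normal jackpots,
frequency-proportional integration with bias, UMI tagging, PCR
duplicates, substitution errors, and Gaussian qualities with optional
bad tails. It does not emulate: indels (off by default), position- or
context-dependent error rates, quality-error correlation (errors are
drawn independently of the emitted qualities), chimeric reads, index
hopping, paired ends, or any array biology beyond the founder/copy
abstraction. Passing tests therefore demonstrate correctness of the
analysis under this model, not robustness to every artifact of real
instruments; the processing stages that handle real-data artifacts
(NextSeq poly-G, quality tails, flank mismatches) are exercised by
targeted fixtures instead.

# Problem sizes and numerical choices

The test and acceptance workloads run at desk scale, chosen as the
smallest sizes at which the distributional checks have power: libraries
of $2\times10^4$–$10^5$ molecules, arrays of 91 (and 3001 for the CV
comparison), read depths of 300–20,000, 4 × 50,000 integrants, 100-seed
replications for the GOF and outlier-recovery rates, and 200 random
instances for the clustering oracle equivalence. Tolerances follow the
sampling distributions involved (3–4 standard deviations of the relevant
statistic) rather than fixed percentages. Determinism: every stochastic
stage takes a seed; stage substreams are derived by a fixed integer hash
of the stage name, all below $2^{31}$.

# Known limitations

* The greedy clustering is order-deterministic but, like all greedy
  sphere clusterings, not globally optimal; the oracle tests pin the
  rule, not an optimum.
* The ZTP GOF requires enough mass per bin (expected ≥ 5 after tail
  merging); for very small arrays it is reported as `NA` rather than
  force-fitted.
* The plateau threshold assumes a count histogram in which an error tail
  and a signal plateau are separated; pathological histograms fall back
  to the fixed default with a warning.
* The frequency-CV diversity comparison is an equality-within-noise
  statement under this generative model, as explained above.
* `demultiplex()` matches indices exactly (header field or 5′ prefix);
  no mismatch-tolerant index assignment is provided.
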