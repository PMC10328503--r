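# tardisbarseq

Simulation and quantification of barcode amplicon sequencing for TARDIS
(Transgenic Arrays Resulting in Diversity of Integrated Sequences)
libraries in *Caenorhabditis elegans*.

TARDIS transgenesis proceeds in two steps: a highly diverse synthetic
library — 15 bp barcodes drawn from the degenerate template
`NNNCNNTNTNANNNN` (11 randomized positions, 4 fixed bases, a space of
4^11 ≈ 4.2 million sequences) — is first carried as a heritable
extrachromosomal array, and single barcodes are then integrated from the
array into an engineered genomic landing pad. Quantifying this process
from amplicon sequencing raises a chain of statistical questions that this
package answers for people running or modeling such experiments:

* **How diverse is the library, the array, and the set of integrants?**
  Reads are quality-trimmed (3′ running-sum trim at Q30), filtered
  (no `N`, expected errors Σ 10^(−Q/10) ≤ 1), cropped to 87 bp,
  UMI-deduplicated (`CAC` + 10 nt UMI + `GAC` block), trimmed to 15 bp
  barcodes, and error-corrected by abundance-greedy Levenshtein sphere
  clustering (radius 2, 5:1 merge ratio). A plateau rule on the
  unique-barcode count u(c) across count cutoffs c picks a conservative
  read threshold (fallback 5).
* **Which sequences are "jackpotted"?** PCR is modeled with per-template
  Beta-distributed duplication efficiencies compounded over binomial
  doubling cycles; the jackpot report lists barcodes above a count cutoff
  (default 50) with the read and unique-barcode fractions they carry.
* **Does array composition follow the proposed model?** Array formation is
  founder sampling with zero-truncated Poisson (ZTP) copy numbers; the
  package fits λ by inverting λ/(1 − e^(−λ)) = x̄ (maximum likelihood) and
  reports a χ² goodness of fit.
* **Does integration track array frequency?** Integrants are multinomial
  draws with optional per-barcode bias; `array_f1_correlation()` computes
  per-replicate and pooled Pearson r (with log-space p-values, so values
  like 10^−154 stay reportable) and flags *replicated outliers* —
  barcodes with |studentized residual| > 3 in ≥ 3 replicates, found by
  sequential deletion so a gross outlier cannot mask a smaller one.

The generative simulator (`sample_library()` → `simulate_pcr()` →
`form_array()` → `draw_integrants()` → `generate_reads()`) produces
UMI-tagged Phred+33 FASTQ with a ground-truth sidecar, so the entire
analysis chain is testable without any external data.

## Worked example

```r
library(tardisbarseq)

tpl <- barcode_template()            # NNNCNNTNTNANNNN
enumerate_space(tpl)                 # 4194304

lib <- sample_library(tpl, 100000, seed = 1)        # oligo library
mix <- simulate_pcr(lib, cycles = 10, seed = 1)     # injection mix
arr <- form_array(mix, m = 91, lambda = 3, seed = 1)
gen <- generate_reads(arr, amplicon_layout(), depth = 20000, seed = 1)

filt <- filter_and_crop(gen$reads)
umi  <- extract_umi(filt$reads)
raw  <- trim_to_barcode(deduplicate(umi$umi_reads))
cl   <- cluster_barcodes(raw$counts)
cl
#> <cluster_result> 91 centroids (21,537 counts), 0 length-filtered (0 counts)

counts <- dplyr::rename(cl$centroids, barcode = "centroid")
prof <- sample_profile(counts, select_threshold(counts$count)$threshold)
summarize_diversity(prof)
#>   n_unique n_reads max_freq min_freq freq_cv
#> 1       91   21537   0.0301  0.00293   0.541

fit_zt_poisson(arr$count)[c("lambda", "p_value")]
#> $lambda  2.984      $p_value  0.571

f1 <- lapply(1:4, function(k)
  sample_profile(draw_integrants(arr, 50000, seed = 100 + k), 5))
res <- array_f1_correlation(sample_profile(arr, 1), f1)
sprintf("pooled r = %.4f, log10 p = %.1f", res$pooled$r, res$pooled$log10_p)
#> "pooled r = 0.9971, log10 p = -407.5"
```

Reading the output: all 91 simulated founders are recovered as centroids
with no spurious barcodes; the fitted copy-number rate λ̂ ≈ 2.98 matches
the simulated ZTP(3); and integrant frequencies track array frequencies
nearly perfectly (r ≈ 0.997) because 4 × 50,000 multinomial draws leave
little sampling noise — biological runs sit lower (r ≈ 0.96) but in the
same regime.

`run_pipeline(tardis_config(), out_dir)` executes the whole chain
(simulate → process → cluster → stats) as one deterministic command and
writes TSV/JSON artifacts plus a conservation ledger;
`inst/cli/tardis-barseq` is a thin shell wrapper over the same functions.

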