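Package: tardisbarseq
Title: Simulation and Quantification of TARDIS Barcode Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for amplicon barcode sequencing of TARDIS (Transgenic
    Arrays Resulting in Diversity of Integrated Sequences) libraries in
    Caenorhabditis elegans. Provides a generative simulator of the
    degenerate-oligo library, PCR jackpotting, extrachromosomal array
    formation with zero-truncated Poisson copy numbers, frequency-
    proportional genomic integration, and UMI-tagged FASTQ reads; a read
    processing pipeline (quality trimming, expected-error filtering, UMI
    extraction and deduplication, barcode trimming); abundance-greedy
    Levenshtein clustering for barcode error correction; and diversity
    statistics including plateau-based count thresholds, jackpot reports,
    position probability matrices, cross-sample overlap, zero-truncated
    Poisson fits, and array-versus-integrant frequency correlation with
    replicated-outlier detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Biostrings,
    ShortRead,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
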