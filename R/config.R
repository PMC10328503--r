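#' Pipeline configuration
#'
#' Builds the declarative configuration for an end-to-end run. Defaults
#' mirror the study conditions of the barcode experiment: a 15 bp template
#' with 11 free positions, 10 PCR cycles, a 91-founder array with
#' zero-truncated Poisson(3) copy numbers, 50,000 integrants, 87 bp reads
#' with a `CAC` + 10 nt UMI + `GAC` block, Q30 trimming with max expected
#' error 1, clustering radius 2 with merge ratio 5, a count threshold with
#' fallback 5, and a jackpot cutoff of 50. Any field can be overridden by
#' passing a nested list; configurations round-trip through YAML.
#'
#' @param ... Named sections (`simulate`, `process`, `cluster`, `stats`,
#'   `seed`) whose entries override the defaults.
#' @return A nested list of class `tardis_config`.
#' @export
tardis_config <- function(...) {
  defaults <- list(
    seed = 1L,
    simulate = list(
      enabled = TRUE,
      template = "NNNCNNTNTNANNNN",
      n_library_molecules = 100000L,
      pcr_cycles = 10L,
      efficiency_beta = c(20, 5),
      n_founders = 91L,
      copy_lambda = 3,
      jackpot_prob = 0,
      jackpot_factor_log_sd = 1,
      n_integrants = 50000L,
      depth = 20000L,
      error_rate = 0.001,
      duplicate_rate = 0.5,
      quality_mean = 36,
      quality_sd = 3,
      low_quality_tail_prob = 0
    ),
    process = list(
      quality_threshold = 30L,
      max_expected_error = 1.0,
      crop_length = 87L,
      umi_flank_5 = "CAC",
      umi_length = 10L,
      umi_flank_3 = "GAC",
      barcode_length = 15L,
      nextseq_mode = FALSE,
      quality_filter_mode = "trim3_then_ee",
      umi_flank_mismatch = 0L
    ),
    cluster = list(
      radius = 2L,
      merge_ratio = 5,
      required_length = 15L
    ),
    stats = list(
      threshold_window = 3L,
      threshold_tol = 0.01,
      default_threshold = 5L,
      jackpot_cutoff = 50L,
      outlier_z = 3,
      outlier_min_replicates = 3L,
      correlation_universe = "union_zero_fill",
      logo_weighting = "unique"
    )
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad) > 0L) {
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- defaults
  for (sec in names(overrides)) {
    if (is.list(defaults[[sec]])) {
      bad <- setdiff(names(overrides[[sec]]), names(defaults[[sec]]))
      if (length(bad) > 0L) {
        stop("unknown config key(s) in ", sec, ": ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      out[[sec]][names(overrides[[sec]])] <- overrides[[sec]]
    } else {
      out[[sec]] <- overrides[[sec]]
    }
  }
  structure(out, class = "tardis_config")
}

#' Read / write a configuration as YAML
#'
#' @param config A [tardis_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   validated [tardis_config()]. Load, dump and reload yield identical
#'   configurations.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "tardis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(tardis_config, raw)
}
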