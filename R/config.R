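#' Default run configuration
#'
#' All numeric knobs of the pipeline in one nested list: exclusion bands,
#' idealization parameters, histogram parameters, simulator scenario
#' parameters and the master seed. The structure round-trips through YAML
#' via [read_config()]/[write_config()].
#'
#' @param seed master RNG seed (integer).
#' @return a list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    bands = list(f_low = 2, line_center = 50, line_halfwidth = 1,
                 f_high = 500),
    ideal = list(k_sigma = 3, min_dwell_ms = 10),
    hist = list(bin_pa = 1, prominence_frac = 0.05),
    sim = list(scenario = "multistate",
               duration_s = 60, v_cis_mv = -80,
               sampling_rate_hz = 10000, filter_cutoff_hz = 500,
               g_open_ps = 500, g_sub_ps = 300, g_top_ps = 1300,
               g_flicker_ps = 600,
               n_hill = 1.17, k_half_mm = 0.6, po_max = 0.2, k_close = 50,
               sigma_white_pa = 1.5, line_amp_pa = 1, line_freq_hz = 50,
               drift_amp_pa = 0.3, drift_corner_hz = 0.5, offset_pa = 0,
               ca_list_mm = c(0.1, 0.25, 0.5, 1, 2, 3),
               replicates = c(4, 4, 4, 4, 4, 3),
               bz423_mm = 0.15, phaso_mm = 0),
    format = "atf",
    seed = as.integer(seed)), class = "run_config")
}

#' Validate a run configuration
#'
#' @param config a `run_config` list.
#' @return character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  v <- character(0)
  pos <- function(val, name) {
    if (!all(is.finite(val)) || any(val <= 0)) {
      v <<- c(v, sprintf("%s: must be strictly positive", name))
    }
  }
  pos(config$ideal$k_sigma, "ideal$k_sigma")
  pos(config$hist$bin_pa, "hist$bin_pa")
  pos(config$sim$duration_s, "sim$duration_s")
  pos(config$sim$sampling_rate_hz, "sim$sampling_rate_hz")
  if (!is.finite(config$seed) || config$seed != round(config$seed)) {
    v <- c(v, "seed: must be an integer")
  }
  if (config$sim$sampling_rate_hz < 2 * config$sim$filter_cutoff_hz) {
    v <- c(v, "sim: sampling_rate_hz must be >= 2 * filter_cutoff_hz")
  }
  v
}

#' Read a run configuration from YAML
#'
#' Keys present in the file override the defaults; everything else keeps its
#' default value.
#'
#' @param path YAML file.
#' @return a `run_config` list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_into <- function(base, over) {
    for (k in names(over)) {
      if (is.list(base[[k]]) && is.list(over[[k]])) {
        base[[k]] <- merge_into(base[[k]], over[[k]])
      } else {
        base[[k]] <- over[[k]]
      }
    }
    base
  }
  out <- merge_into(unclass(cfg), user)
  out$seed <- as.integer(out$seed)
  structure(out, class = "run_config")
}

#' Write a run configuration to YAML
#'
#' @param config a `run_config` list.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
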