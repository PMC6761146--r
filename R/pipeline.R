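# Scenario builders used by the pipeline and by make_fixtures() -----------

#' Default multi-substate scenario
#'
#' The packaged complex-activity scenario: closed / 300 pS substate /
#' 1300 pS full-open / brief 600 pS flicker gating at -80 mV under
#' 3 mM Ca2+ + 0.1 mM Bz-423 + 0.2 mM PhAsO, 60 s at 10 kHz with a 500 Hz
#' low-pass, 2 pA post-filter noise, 1 pA line interference and slow drift.
#'
#' @param duration_s recording length (s).
#' @param v_cis_mv holding potential (mV).
#' @param sigma_white_pa post-filter noise SD (pA).
#' @return a [sim_scenario()].
#' @export
scenario_multistate <- function(duration_s = 60, v_cis_mv = -80,
                                sigma_white_pa = 2) {
  sim_scenario(
    gating = multistate_scheme(),
    noise = noise_model(sigma_white = sigma_white_pa, line_amp = 1,
                        drift_amp = 0.5, drift_corner = 0.5, offset_pa = 0),
    v_cis = v_cis_mv, duration = duration_s,
    condition = condition_label(ca_mm = 3, bz423_mm = 0.1, phaso_mm = 0.2))
}

#' Default Ca2+-titration scenario template
#'
#' Two-state gating (closed / 500 pS open) whose opening rate follows a
#' Hill-type Ca2+ activation, recorded at -60 mV in the presence of
#' 0.15 mM Bz-423. The activation's half-activation (0.6 mM), asymptotic
#' open probability (0.2) and closing rate (50 s^-1) are package defaults
#' chosen as realistic for a modest-Po megachannel titrated over 0.1-3 mM;
#' the Hill coefficient is the caller's choice.
#'
#' @param n_hill generating Hill coefficient.
#' @param k_half_mm half-activation Ca2+ (mM).
#' @param po_max asymptotic open probability.
#' @param k_close closing rate (s^-1).
#' @param g_open_ps open-state conductance (pS).
#' @param duration_s recording length (s).
#' @param v_cis_mv holding potential (mV).
#' @param sigma_white_pa post-filter noise SD (pA).
#' @return a [sim_scenario()] carrying a [ca_activation()].
#' @export
scenario_titration <- function(n_hill = 1.17, k_half_mm = 0.6, po_max = 0.2,
                               k_close = 50, g_open_ps = 500,
                               duration_s = 60, v_cis_mv = -60,
                               sigma_white_pa = 1.5) {
  sim_scenario(
    gating = two_state_scheme(g_open_ps, k_open = 0, k_close = k_close),
    noise = noise_model(sigma_white = sigma_white_pa, line_amp = 1,
                        drift_amp = 0.3, drift_corner = 0.5, offset_pa = 0),
    v_cis = v_cis_mv, duration = duration_s,
    activation = ca_activation(n_hill, k_half_mm, po_max, k_close),
    condition = condition_label(ca_mm = 0, bz423_mm = 0.15))
}

scenario_from_config <- function(config) {
  s <- config$sim
  noise <- noise_model(sigma_white = s$sigma_white_pa,
                       line_amp = s$line_amp_pa, line_freq = s$line_freq_hz,
                       drift_amp = s$drift_amp_pa,
                       drift_corner = s$drift_corner_hz,
                       offset_pa = s$offset_pa)
  if (s$scenario == "multistate") {
    sc <- scenario_multistate(s$duration_s, s$v_cis_mv)
    sc$noise <- noise
    sc$sampling_rate <- s$sampling_rate_hz
    sc$filter_cutoff <- s$filter_cutoff_hz
    sc
  } else if (s$scenario %in% c("titration", "two_state")) {
    sc <- scenario_titration(n_hill = s$n_hill, k_half_mm = s$k_half_mm,
                             po_max = s$po_max, k_close = s$k_close,
                             g_open_ps = s$g_open_ps,
                             duration_s = s$duration_s,
                             v_cis_mv = s$v_cis_mv)
    sc$noise <- noise
    sc$sampling_rate <- s$sampling_rate_hz
    sc$filter_cutoff <- s$filter_cutoff_hz
    sc$condition$bz423_mm <- s$bz423_mm
    sc$condition$phaso_mm <- s$phaso_mm
    sc
  } else {
    stop("validation error: unknown scenario '", s$scenario, "'")
  }
}

write_manifest <- function(out_dir, config, files, timings = NULL) {
  lines <- c(sprintf("software=bilayerPSA %s",
                     as.character(utils::packageVersion("bilayerPSA"))),
             sprintf("seed=%d", config$seed),
             sprintf("scenario=%s", config$sim$scenario))
  if (length(files)) {
    md5 <- tools::md5sum(files)
    lines <- c(lines, sprintf("file=%s md5=%s", basename(files), md5))
  }
  if (!is.null(timings)) {
    lines <- c(lines, sprintf("timing_%s_s=%.3f", names(timings), timings))
  }
  writeLines(lines, file.path(out_dir, "manifest.txt"))
  invisible(file.path(out_dir, "manifest.txt"))
}

#' Simulate traces according to a configuration
#'
#' Materializes the configured scenario into trace files: a single recording
#' for the `multistate` and `two_state` scenarios, or the full Ca2+ series
#' for `titration` (`replicates x length(ca_list_mm)` files). All files are
#' reproducible byte-for-byte given (config, seed). Parameters are validated
#' before any file is written.
#'
#' @param config a [default_config()]-style list.
#' @param out_dir output directory (created if missing).
#' @return character vector of written trace paths (plus a manifest in
#'   `out_dir`).
#' @export
run_simulate <- function(config, out_dir) {
  v <- validate_config(config)
  if (length(v)) stop("validation error: ", paste(v, collapse = "; "))
  sc <- scenario_from_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (config$format == "atf") "atf" else "csv"
  t0 <- proc.time()[["elapsed"]]
  paths <- character(0)
  if (config$sim$scenario == "titration") {
    ca <- config$sim$ca_list_mm
    reps <- config$sim$replicates
    if (length(reps) == 1) reps <- rep(reps, length(ca))
    traces <- simulate_titration(sc, ca, reps, seed = config$seed)
    k <- 0
    for (i in seq_along(ca)) {
      for (r in seq_len(reps[i])) {
        k <- k + 1
        p <- file.path(out_dir, sprintf("trace_ca%.3f_rep%d.%s", ca[i], r, ext))
        write_trace(traces[[k]], p)
        paths <- c(paths, p)
      }
    }
  } else {
    tr <- simulate_trace(sc, seed = config$seed)
    p <- file.path(out_dir, sprintf("trace_%s.%s", config$sim$scenario, ext))
    write_trace(tr, p)
    paths <- p
  }
  write_manifest(out_dir, config, paths,
                 timings = c(simulate = proc.time()[["elapsed"]] - t0))
  paths
}

#' Analyze a batch of trace files
#'
#' Reads every input, computes the per-trace [analyze_trace()] metrics row
#' and stacks them into one table. Unreadable or invalid files are flagged
#' (with the error message) and skipped; the run only fails when no input
#' is readable.
#'
#' @param paths trace file paths.
#' @param config a [default_config()]-style list.
#' @param out_dir optional; when given, writes `metrics.csv` plus per-trace
#'   spectrum and histogram CSVs there.
#' @return the metrics data.frame (one row per readable trace, with a
#'   `file` column); attribute `failures` is a data.frame of skipped files.
#' @export
run_analyze <- function(paths, config = default_config(), out_dir = NULL) {
  if (!length(paths)) stop("run error: no input traces")
  rows <- list(); fails <- list()
  for (p in paths) {
    res <- tryCatch({
      tr <- read_trace(p)
      m <- analyze_trace(tr, config)
      m$file <- basename(p)
      m
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <-
        data.frame(file = basename(p), error = conditionMessage(res))
    } else {
      if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        stem <- sub("\\.[A-Za-z0-9]+$", "", basename(p))
        sp <- attr(res, "spectrum")
        if (!is.null(sp)) {
          write_spectrum_csv(sp, file.path(out_dir,
                                           paste0(stem, "_spectrum.csv")))
        }
        id <- attr(res, "ideal")
        if (!is.null(id) && nrow(id$events)) {
          utils::write.csv(id$events[, c("start_s", "end_s", "mean_pa")],
                           file.path(out_dir, paste0(stem, "_events.csv")),
                           row.names = FALSE)
        }
        hg <- attr(res, "histogram")
        if (!is.null(hg)) {
          centers <- (hg$bin_edges[-1] + hg$bin_edges[-length(hg$bin_edges)]) / 2
          utils::write.csv(data.frame(bin_center_pa = centers,
                                      count = hg$counts),
                           file.path(out_dir, paste0(stem, "_histogram.csv")),
                           row.names = FALSE)
        }
      }
      rows[[length(rows) + 1L]] <- as.data.frame(res)
    }
  }
  if (!length(rows)) stop("run error: zero readable inputs")
  metrics <- do.call(rbind, rows)
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(file = character(0), error = character(0))
  if (!is.null(out_dir)) {
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    if (nrow(failures)) {
      utils::write.csv(failures, file.path(out_dir, "failures.csv"),
                       row.names = FALSE)
    }
  }
  attr(metrics, "failures") <- failures
  metrics
}

#' Fit dose-response, current-voltage and group-comparison reports
#'
#' From a metrics table: Hill fits of PSA and Po versus Ca2+ (skipped, with
#' a logged reason, when fewer than 4 distinct positive concentrations are
#' present), a linear I-V fit of the mean open current when 3 or more
#' voltages are present, and pairwise Mann-Whitney comparisons when 2 or
#' more condition groups are present.
#'
#' @param metrics metrics data.frame from [run_analyze()].
#' @param config a [default_config()]-style list.
#' @param out_dir optional; when given, writes `hill_psa.json`,
#'   `hill_po.json`, `iv_fit.json` and `comparisons.csv` there.
#' @return list with elements `hill` (per-statistic [hill_fit()]s), `iv`,
#'   `comparisons` and `notes`.
#' @export
run_fit <- function(metrics, config = default_config(), out_dir = NULL) {
  notes <- character(0)
  hill <- list()
  n_ca <- length(unique(metrics$ca_mm[metrics$ca_mm > 0]))
  if (n_ca >= 4) {
    for (stat in c("psa_pa2", "po")) {
      tb <- titration_table(metrics, stat)
      hill[[stat]] <- hill_fit(tb)
    }
  } else {
    notes <- c(notes, sprintf(
      "hill: skipped (%d distinct positive Ca2+ concentrations < 4)", n_ca))
  }
  iv <- NULL
  volt <- unique(metrics$v_cis_mv[is.finite(metrics$v_cis_mv)])
  if (length(volt) >= 3) {
    pts <- stats::aggregate(
      list(i_pa = ifelse(is.finite(metrics$g_mean_ps),
                         metrics$g_mean_ps * metrics$v_cis_mv / 1000, 0)),
      by = list(v_mv = metrics$v_cis_mv), FUN = mean)
    iv <- iv_fit(pts)
  }
  comparisons <- NULL
  lab <- sprintf("Ca%g/Bz%g/PhAsO%g/%s", metrics$ca_mm, metrics$bz423_mm,
                 metrics$phaso_mm, metrics$inhibitor)
  if (length(unique(lab)) >= 2) {
    comparisons <- compare_conditions(metrics, "condition")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (stat in names(hill)) {
      jsonlite::write_json(
        unclass(hill[[stat]]),
        file.path(out_dir, sprintf("hill_%s.json",
                                   sub("_pa2$", "", stat))),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    if (!is.null(iv)) {
      jsonlite::write_json(unclass(iv)[c("slope_conductance_ps", "offset_pa",
                                         "r2")],
                           file.path(out_dir, "iv_fit.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    if (!is.null(comparisons)) {
      utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE)
    }
    if (length(notes)) writeLines(notes, file.path(out_dir, "fit_notes.txt"))
  }
  list(hill = hill, iv = iv, comparisons = comparisons, notes = notes)
}

#' Run simulate -> analyze -> fit end to end
#'
#' @param config a [default_config()]-style list.
#' @param out_dir run directory; traces land in `<out_dir>/traces`, tables
#'   and reports in `<out_dir>/analysis`.
#' @return the [run_fit()] report list (metrics attached as attribute
#'   `metrics`).
#' @export
run_all <- function(config, out_dir) {
  paths <- run_simulate(config, file.path(out_dir, "traces"))
  metrics <- run_analyze(paths, config, file.path(out_dir, "analysis"))
  fit <- run_fit(metrics, config, file.path(out_dir, "analysis"))
  attr(fit, "metrics") <- metrics
  fit
}

#' Materialize packaged example scenarios
#'
#' `multistate`: one 60 s complex-activity recording at -80 mV.
#' `titration`: the 23-recording Ca2+ series (6 concentrations, 0.1-3 mM).
#' `iv`: an exactly linear current-voltage point series (500 pS slope) with
#' a 13 pA constant gradient offset, as `iv_points.csv`.
#'
#' @param name one of "multistate", "titration", "iv".
#' @param out_dir output directory.
#' @param seed integer seed.
#' @return character vector of written paths.
#' @export
make_fixtures <- function(name = c("multistate", "titration", "iv"),
                          out_dir, seed = 1L) {
  name <- match.arg(name)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (name == "iv") {
    v <- c(-80, -60, -40, -20, 0, 20)
    pts <- data.frame(v_mv = v, i_pa = 0.5 * v + 13)
    p <- file.path(out_dir, "iv_points.csv")
    utils::write.csv(pts, p, row.names = FALSE)
    return(p)
  }
  cfg <- default_config(seed)
  cfg$sim$scenario <- name
  if (name == "titration") cfg$sim$v_cis_mv <- -60
  run_simulate(cfg, out_dir)
}
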