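# Peak detection on histogram counts: counts are zero-padded at both ends
# (so peaks in the first/last bin are detectable) and lightly smoothed with
# a 3-bin running mean before find_peaks(). Returns (index, height,
# prominence) with indices into the original count vector.
smoothed_hist_peaks <- function(counts) {
  padded <- c(0, 0, counts, 0, 0)
  sm <- as.numeric(stats::filter(padded, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- 0
  pk <- find_peaks(sm)
  pk$index <- pk$index - 2L
  pk[pk$index >= 1L & pk$index <= length(counts), , drop = FALSE]
}

# Robust scale of a sample vector that degrades gracefully for noise-free
# (quantized) data: MAD, then IQR, then a fraction of the SD, then a floor.
robust_scale <- function(x) {
  s <- stats::mad(x)
  if (s > 0) return(s)
  s <- stats::IQR(x) / 1.349
  if (s > 0) return(s)
  s <- stats::sd(x) / 10
  if (is.finite(s) && s > 0) return(s)
  1e-6
}

# SD shrinkage of a normal truncated at +/- c sigma; used to de-bias the
# core-window SD when fitting the closed-peak Gaussian.
trunc_sd_factor <- function(c) {
  z <- 2 * stats::pnorm(c) - 1
  sqrt(max(1e-12, 1 - 2 * c * stats::dnorm(c) / z))
}

#' Estimate the closed-state baseline and noise SD
#'
#' Finds the dominant peak of the sample amplitude distribution nearest 0 pA
#' (the closed level) and fits a Gaussian to that peak's own core: the
#' contiguous histogram bins whose counts stay above half of the peak height
#' (descending monotonically, so the fit never reaches into a neighbouring
#' conducting level). The fitted mean is the baseline and the fitted SD the
#' noise sigma; a truncation-corrected moment estimate is the fallback when
#' the core spans too few bins. Noise-free records degrade to a zero-width
#' peak; the returned sigma is floored at 1e-6 pA so threshold idealization
#' stays defined.
#'
#' @param trace a [current_trace()] with >= 1000 samples.
#' @return list with `baseline` (pA) and `noise_sigma` (pA).
#' @export
estimate_baseline <- function(trace) {
  assert_trace(trace)
  x <- trace$samples
  if (length(x) < 1000) stop("estimate_baseline needs >= 1000 samples")
  s0 <- robust_scale(x)
  rng <- range(x)
  # cap the grid at 2000 bins: noise-free filtered records have MAD near the
  # floating-point floor, which would otherwise ask for astronomical grids
  bw <- max(s0 / 4, diff(rng) / 2000)
  if (diff(rng) < bw) { # (almost) constant record
    return(list(baseline = stats::median(x), noise_sigma = 1e-6))
  }
  brk <- seq(rng[1] - bw, rng[2] + bw, by = bw)
  h <- graphics::hist(x, breaks = brk, plot = FALSE)
  pk <- smoothed_hist_peaks(h$counts)
  if (!nrow(pk)) { # single-bin spike distributions
    pk <- data.frame(index = which.max(h$counts),
                     height = max(h$counts), prominence = max(h$counts))
  }
  centers <- h$mids[pk$index]
  near <- abs(centers) <= max(5 * s0, 2 * bw)
  if (!any(near)) {
    stop("baseline-not-found: no amplitude peak within 5 robust SDs of 0 pA ",
         "(never-closed or offset-corrupted record?)")
  }
  # dominant candidate peak; among near-equal heights (within 5%) take the
  # one nearest 0 pA, so symmetric two-level records resolve to the closed
  # level at baseline
  ch <- pk$height[near]; cc <- centers[near]
  top <- ch >= 0.95 * max(ch)
  pick <- which(near)[top][which.min(abs(cc[top]))]
  b <- centers[near][top][which.min(abs(cc[top]))]
  # Gaussian fit anchored to the peak's own footprint: take the contiguous
  # run of bins around the peak whose (smoothed) counts stay above half of
  # the peak height -- this never reaches into a neighbouring conducting
  # level, which sits behind a valley -- and fit A exp(-(x-mu)^2 / 2 s^2)
  # to the raw counts there.
  padded <- c(0, 0, h$counts, 0, 0)
  sm <- as.numeric(stats::filter(padded, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- 0
  sm <- sm[3:(length(sm) - 2)]
  p_i <- pk$index[pick]
  h0 <- max(sm[p_i], h$counts[p_i])
  lo_i <- p_i
  while (lo_i > 1 && sm[lo_i - 1] >= 0.5 * h0 && sm[lo_i - 1] <= sm[lo_i]) {
    lo_i <- lo_i - 1
  }
  hi_i <- p_i
  nb <- length(sm)
  while (hi_i < nb && sm[hi_i + 1] >= 0.5 * h0 && sm[hi_i + 1] <= sm[hi_i]) {
    hi_i <- hi_i + 1
  }
  lo_i <- max(1, lo_i - 1)
  hi_i <- min(nb, hi_i + 1)
  core <- lo_i:hi_i
  hw <- max(h$mids[hi_i] - b, b - h$mids[lo_i], bw)
  s_hat <- NA_real_
  if (length(core) >= 4) {
    df <- data.frame(xm = h$mids[core], ct = h$counts[core])
    # warnOnly keeps near-converged fits usable; the estimate is validated
    # against the peak location below, so the convergence chatter is muted
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(ct ~ A * exp(-(xm - mu)^2 / (2 * s^2)), data = df,
                   start = list(A = max(df$ct), mu = b,
                                s = max(hw / 1.7, bw / 2)),
                   control = stats::nls.control(warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      if (is.finite(cf[["s"]]) && abs(cf[["s"]]) > 0 &&
          abs(cf[["mu"]] - b) <= 3 * bw + abs(cf[["s"]])) {
        b <- cf[["mu"]]
        s_hat <- abs(cf[["s"]])
      }
    }
  }
  if (!is.finite(s_hat)) {
    # moment fallback on the peak footprint, de-biased for the truncation
    sel <- x[abs(x - b) <= hw]
    if (length(sel) >= 50) {
      b <- stats::median(sel)
      if (stats::mad(sel) <= 1e-9 * max(1, abs(b))) {
        # spike distribution (noise-free record): zero-width peak
        return(list(baseline = unname(b), noise_sigma = 1e-6))
      }
      sdo <- stats::sd(sel)
      if (is.finite(sdo) && sdo > 1e-9) {
        root <- tryCatch(
          stats::uniroot(function(s) s * trunc_sd_factor(hw / s) - sdo,
                         lower = sdo, upper = 2 * hw, tol = 1e-9 * sdo),
          error = function(e) NULL)
        s_hat <- if (is.null(root)) sdo else min(root$root, hw)
      }
    }
  }
  if (!is.finite(s_hat)) s_hat <- 1e-6
  list(baseline = unname(b), noise_sigma = max(unname(s_hat), 1e-6))
}

#' Threshold idealization of a trace
#'
#' A sample is open when its current lies outside the noise band around the
#' closed baseline: `|x - baseline| > k_sigma * noise_sigma`. Open epochs
#' (events) are the maximal runs of open samples. Each event's level is
#' estimated as the mean of its samples lying within the noise band around
#' the event median, which discards filter-edge transition samples without a
#' fixed trim.
#'
#' @param trace a [current_trace()].
#' @param k_sigma noise-band multiplier (default 3: ~0.3\% false-open time
#'   per tail for Gaussian noise).
#' @return an object of class `idealized_trace`: open flags, baseline,
#'   noise_sigma, noise-band half-width, the event table (`start_s`,
#'   `end_s`, `n_samples`, `mean_pa` = level estimate relative to 0,
#'   `sign`), plus the samples and sampling rate for downstream estimators.
#' @export
idealize <- function(trace, k_sigma = 3) {
  stopifnot(k_sigma > 0)
  bl <- estimate_baseline(trace)
  x <- trace$samples
  dt <- 1 / trace$sampling_rate
  half <- k_sigma * bl$noise_sigma
  open <- abs(x - bl$baseline) > half
  r <- rle(open)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  oi <- which(r$values)
  ev <- data.frame(start_s = (starts[oi] - 1L) * dt, end_s = ends[oi] * dt,
                   n_samples = r$lengths[oi],
                   mean_pa = rep(NA_real_, length(oi)),
                   sign = rep(NA_real_, length(oi)))
  if (nrow(ev)) {
    lev <- numeric(nrow(ev))
    for (k in seq_len(nrow(ev))) {
      seg <- x[starts[oi[k]]:ends[oi[k]]]
      med <- stats::median(seg)
      core <- seg[abs(seg - med) <= half]
      lev[k] <- if (length(core)) mean(core) else med
    }
    ev$mean_pa <- lev
    ev$sign <- sign(lev - bl$baseline)
  }
  structure(list(open_flags = open, baseline = bl$baseline,
                 noise_sigma = bl$noise_sigma,
                 noise_band_halfwidth = half, events = ev,
                 samples = x, sampling_rate = trace$sampling_rate,
                 event_bounds = cbind(start = starts[oi], end = ends[oi])),
            class = "idealized_trace")
}

#' @export
print.idealized_trace <- function(x, ...) {
  cat(sprintf(
    "idealized_trace: baseline %.3g pA, sigma %.3g pA, band +/-%.3g pA, %d events\n",
    x$baseline, x$noise_sigma, x$noise_band_halfwidth, nrow(x$events)))
  invisible(x)
}

#' Open probability
#'
#' Fraction of the recording time spent outside the noise band: open samples
#' times the sampling interval over the whole recording time.
#'
#' @param ideal an [idealize()] result.
#' @param duration recording time (s); defaults to the idealized record's
#'   own length.
#' @return open probability in \[0, 1\].
#' @export
compute_po <- function(ideal, duration = NULL) {
  dt <- 1 / ideal$sampling_rate
  if (is.null(duration)) duration <- length(ideal$open_flags) * dt
  stopifnot(duration > 0)
  min(1, sum(ideal$open_flags) * dt / duration)
}

# events whose polarity matches the conducting sign implied by v_cis;
# opposite-polarity events are artifacts for conductance purposes.
matching_events <- function(ideal, v_cis) {
  ev <- ideal$events
  if (!nrow(ev)) return(integer(0))
  which(ev$sign == sign(v_cis))
}

#' Mean open-state conductance
#'
#' Average of the whole current signal in the open state (all open samples
#' of conducting-polarity events), converted by Ohm's law:
#' `1000 * |mean(open) - baseline| / |v_cis|`. Opposite-polarity events are
#' excluded (and counted) as artifacts.
#'
#' @param ideal an [idealize()] result.
#' @param v_cis holding potential (mV, non-zero).
#' @return conductance (pS), or NA when there are no open samples.
#' @export
compute_g_mean <- function(ideal, v_cis) {
  if (is.na(v_cis) || v_cis == 0) {
    stop("undefined conductance: v_cis must be non-zero")
  }
  keep <- matching_events(ideal, v_cis)
  if (!length(keep)) return(NA_real_)
  b <- ideal$event_bounds[keep, , drop = FALSE]
  idx <- sequence(b[, "end"] - b[, "start"] + 1L, from = b[, "start"])
  conductance_ps(mean(ideal$samples[idx]) - ideal$baseline, v_cis)
}

#' Maximal stable conductance
#'
#' The conductance of the maximal stable current level: only events lasting
#' at least `min_dwell_ms` are considered, and within each such event the
#' level is measured on `min_dwell_ms`-long windows whose sample SD does not
#' exceed 1.5 times the closed-state noise SD (a window straddling a level
#' transition, a filter edge or its overshoot fails this gate); consecutive
#' passing windows are merged into maximal stable stretches, each averaged
#' whole. The reported value is the largest
#' `1000 * |stretch mean - baseline| / |v_cis|` over all stable stretches
#' of qualifying conducting-polarity events. An event lasting exactly
#' `min_dwell_ms` qualifies; one sample shorter does not. With
#' `min_dwell_ms = 0` the rule degenerates to the event-mean maximum.
#'
#' @param ideal an [idealize()] result.
#' @param v_cis holding potential (mV, non-zero).
#' @param min_dwell_ms stability dwell requirement (ms, default 10).
#' @return conductance (pS), or NA when no event qualifies.
#' @export
compute_g_max <- function(ideal, v_cis, min_dwell_ms = 10) {
  if (is.na(v_cis) || v_cis == 0) {
    stop("undefined conductance: v_cis must be non-zero")
  }
  fs <- ideal$sampling_rate
  w <- max(1L, as.integer(round(min_dwell_ms / 1000 * fs)))
  keep <- matching_events(ideal, v_cis)
  keep <- keep[ideal$events$n_samples[keep] >= w]
  if (!length(keep)) return(NA_real_)
  gate <- max(1.5 * ideal$noise_sigma, 1e-9)
  best <- NA_real_
  for (k in keep) {
    seg <- ideal$samples[ideal$event_bounds[k, "start"]:
                           ideal$event_bounds[k, "end"]]
    rs <- rolling_stats(seg, w)
    ok <- if (w >= 2) rs$sd <= gate else rep(TRUE, length(rs$mean))
    if (!any(ok)) next
    # merge consecutive passing windows into maximal stable stretches and
    # average each whole stretch: longer averages suppress the upward
    # selection bias a max over short windows would have
    r2 <- rle(ok)
    e2 <- cumsum(r2$lengths)
    s2 <- e2 - r2$lengths + 1L
    for (j in which(r2$values)) {
      i0 <- s2[j]
      i1 <- e2[j] + w - 1L
      m <- abs(mean(seg[i0:i1]) - ideal$baseline)
      if (is.na(best) || m > best) best <- m
    }
  }
  if (is.na(best)) return(NA_real_)
  conductance_ps(best, v_cis)
}

#' Current amplitude histogram with substate peaks
#'
#' Histogram of all sample amplitudes over uniform bins spanning the data
#' range, with local maxima of the (lightly smoothed) counts reported as
#' peaks when their topographic prominence exceeds a fraction of the modal
#' count. Distinct conducting levels appear as separate peaks.
#'
#' @param trace a [current_trace()].
#' @param bin_width bin width (pA, > 0).
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   maximal count.
#' @return an object of class `amplitude_histogram`: `bin_edges`, `counts`,
#'   and `peaks` (data.frame `level_pa`, `prominence`, sorted by |level|).
#' @export
amplitude_histogram <- function(trace, bin_width = 1, prominence_frac = 0.05) {
  assert_trace(trace)
  stopifnot(bin_width > 0)
  x <- trace$samples
  lo <- floor(min(x) / bin_width) * bin_width - bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width + bin_width
  brk <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(x, breaks = brk, plot = FALSE)
  pk <- smoothed_hist_peaks(h$counts)
  pk <- pk[pk$prominence >= prominence_frac * max(pk$height, h$counts), ,
           drop = FALSE]
  peaks <- data.frame(level_pa = h$mids[pk$index], prominence = pk$prominence)
  peaks <- peaks[order(abs(peaks$level_pa)), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(bin_edges = h$breaks, counts = h$counts, peaks = peaks),
            class = "amplitude_histogram")
}

#' @export
print.amplitude_histogram <- function(x, ...) {
  cat(sprintf("amplitude_histogram: %d bins, %d peaks at %s pA\n",
              length(x$counts), nrow(x$peaks),
              paste(sprintf("%.3g", x$peaks$level_pa), collapse = ", ")))
  invisible(x)
}

#' Full per-trace channel metrics
#'
#' Composition of the PSA and the idealization-based estimators: one metrics
#' row per trace with PSA (pA^2), Po, G_mean and G_max (pS), and the event
#' count. A failed estimator yields an NA field and an attached note rather
#' than an error, so batch analysis continues.
#'
#' @param trace a [current_trace()].
#' @param config a [default_config()]-style configuration list.
#' @return a one-row data.frame of class `channel_metrics` with columns
#'   `ca_mm`, `bz423_mm`, `phaso_mm`, `inhibitor`, `v_cis_mv`, `psa_pa2`,
#'   `po`, `g_mean_ps`, `g_max_ps`, `n_events`; attribute `notes` collects
#'   estimator warnings, `ideal`/`spectrum`/`histogram` the intermediates.
#' @export
analyze_trace <- function(trace, config = default_config()) {
  assert_trace(trace)
  notes <- character(0)
  grab <- function(expr, what) {
    tryCatch(expr, error = function(e) {
      notes <<- c(notes, sprintf("%s: %s", what, conditionMessage(e)))
      NULL
    })
  }
  bands <- band_exclusion(config$bands$f_low, config$bands$line_center,
                          config$bands$line_halfwidth, config$bands$f_high)
  psa <- grab(psa_of_trace(trace, bands), "psa")
  ideal <- grab(idealize(trace, k_sigma = config$ideal$k_sigma), "idealize")
  po <- g_mean <- g_max <- NA_real_
  n_events <- NA_integer_
  if (!is.null(ideal)) {
    po <- compute_po(ideal)
    n_events <- nrow(ideal$events)
    if (po > 0 && is.finite(trace$v_cis) && trace$v_cis != 0) {
      g_mean <- grab(compute_g_mean(ideal, trace$v_cis), "g_mean")
      g_max <- grab(compute_g_max(ideal, trace$v_cis,
                                  config$ideal$min_dwell_ms), "g_max")
      if (is.null(g_mean)) g_mean <- NA_real_
      if (is.null(g_max)) g_max <- NA_real_
    }
  }
  hist <- grab(amplitude_histogram(trace, config$hist$bin_pa,
                                   config$hist$prominence_frac), "histogram")
  out <- data.frame(ca_mm = trace$condition$ca_mm,
                    bz423_mm = trace$condition$bz423_mm,
                    phaso_mm = trace$condition$phaso_mm,
                    inhibitor = trace$condition$inhibitor,
                    v_cis_mv = trace$v_cis,
                    psa_pa2 = if (is.null(psa)) NA_real_ else psa$psa,
                    po = po, g_mean_ps = g_mean, g_max_ps = g_max,
                    n_events = n_events)
  class(out) <- c("channel_metrics", "data.frame")
  attr(out, "notes") <- notes
  attr(out, "ideal") <- ideal
  attr(out, "spectrum") <- if (!is.null(psa)) psa$spectrum
  attr(out, "histogram") <- hist
  out
}
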