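#' One-sided periodogram of a current trace
#'
#' Full-record rectangular-window periodogram of the mean-subtracted signal,
#' normalized so that the integral of the PSD over all frequencies equals the
#' signal's mean-square deviation from its mean (discrete Parseval). The
#' frequency resolution is 1/record_duration. The DC bin is zero by
#' construction (mean subtraction) and is always excluded from the analysis
#' mask.
#'
#' No Welch averaging is applied: the PSA is an integral statistic whose
#' expectation does not depend on windowing, and the analysis convention is a
#' single long window per record.
#'
#' @param trace a [current_trace()] with >= 2 samples.
#' @return an object of class `power_spectrum`: list with `freqs` (Hz,
#'   ascending from 0), `psd` (pA^2/Hz, one-sided), `mask` (retained flag,
#'   DC excluded), `record_duration` (s), `df` (Hz).
#' @export
periodogram <- function(trace) {
  assert_trace(trace)
  x <- trace$samples
  n <- length(x)
  if (n < 2) stop("periodogram needs at least 2 samples")
  fs <- trace$sampling_rate
  x <- x - mean(x)
  X <- stats::fft(x)
  n_one <- floor(n / 2) + 1L
  p <- Mod(X[seq_len(n_one)])^2 / (fs * n)
  scale <- rep(2, n_one)
  scale[1] <- 1
  if (n %% 2 == 0) scale[n_one] <- 1
  psd <- p * scale
  freqs <- (seq_len(n_one) - 1) * fs / n
  mask <- rep(TRUE, n_one)
  mask[1] <- FALSE
  structure(list(freqs = freqs, psd = psd, mask = mask,
                 record_duration = n / fs, df = fs / n),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    "power_spectrum: %d bins, df = %.4g Hz, %d retained, total power %.4g pA^2\n",
    length(x$freqs), x$df, sum(x$mask), sum(x$psd) * x$df))
  invisible(x)
}

#' Frequency exclusion bands for the PSA
#'
#' The analysis convention: frequencies below `f_low` (baseline drift), within
#' `line_halfwidth` of the mains line (power-line interference) and above
#' `f_high` (beyond the analog filter corner) are excluded. Bounds are
#' half-open conventions on the FFT grid: a bin is dropped when
#' `f < f_low`, `|f - line_center| < line_halfwidth` or `f > f_high`, so the
#' 2, 49, 51 and 500 Hz bins themselves are retained at the defaults.
#' Set `line_center = NA` to disable the line notch.
#'
#' @param f_low low cutoff (Hz).
#' @param line_center mains frequency (Hz) or NA.
#' @param line_halfwidth half-width of the line notch (Hz). The default 1 Hz
#'   covers mains wander while removing under 0.5\% of the retained band.
#' @param f_high high cutoff (Hz).
#' @return an object of class `band_exclusion`.
#' @export
band_exclusion <- function(f_low = 2, line_center = 50, line_halfwidth = 1,
                           f_high = 500) {
  stopifnot(f_low >= 0, f_high > f_low, line_halfwidth >= 0)
  if (is.finite(line_center) &&
      (f_low >= line_center - line_halfwidth ||
       line_center + line_halfwidth >= f_high)) {
    stop("parameter error: line band must lie strictly inside (f_low, f_high)")
  }
  structure(list(f_low = f_low, line_center = line_center,
                 line_halfwidth = line_halfwidth, f_high = f_high),
            class = "band_exclusion")
}

#' Apply exclusion bands to a power spectrum
#'
#' Updates the retained-bin mask; PSD values are untouched. The DC bin stays
#' excluded regardless of `f_low`. Applying the same bands twice equals
#' applying them once.
#'
#' @param spectrum a [periodogram()] result.
#' @param bands a [band_exclusion()].
#' @return the spectrum with its mask updated.
#' @export
apply_exclusions <- function(spectrum, bands) {
  stopifnot(inherits(spectrum, "power_spectrum"),
            inherits(bands, "band_exclusion"))
  f <- spectrum$freqs
  keep <- f >= bands$f_low & f <= bands$f_high
  if (is.finite(bands$line_center) && bands$line_halfwidth > 0) {
    keep <- keep & (abs(f - bands$line_center) >= bands$line_halfwidth)
  }
  keep[1] <- FALSE # DC
  spectrum$mask <- keep
  spectrum
}

#' Integrate the retained power spectrum (PSA)
#'
#' The power-spectrum-area statistic: trapezoidal integral of the PSD over
#' the retained frequency set, computed per contiguous retained run (an
#' isolated single bin has zero trapezoidal measure). With no exclusions the
#' PSA equals the trace's mean-square amplitude (Parseval), so it acts as a
#' band-limited activity variance in pA^2.
#'
#' @param spectrum a [power_spectrum] (mask already set).
#' @return an object of class `psa_result`: list with `psa` (pA^2),
#'   `retained_bandwidth` (Hz) and the spectrum.
#' @export
compute_psa <- function(spectrum) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  m <- spectrum$mask
  if (!any(m)) stop("empty retained set: no frequency bins to integrate")
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  psa <- 0
  bw <- 0
  for (k in which(r$values)) {
    i <- starts[k]:ends[k]
    if (length(i) >= 2) {
      f <- spectrum$freqs[i]
      p <- spectrum$psd[i]
      psa <- psa + sum((p[-1] + p[-length(p)]) / 2 * diff(f))
      bw <- bw + (f[length(f)] - f[1])
    }
  }
  structure(list(psa = psa, retained_bandwidth = bw, spectrum = spectrum),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("psa_result: PSA = %.6g pA^2 over %.4g Hz retained bandwidth\n",
              x$psa, x$retained_bandwidth))
  invisible(x)
}

#' PSA of a trace in one call
#'
#' Composition periodogram -> exclusions -> integration.
#'
#' @param trace a [current_trace()].
#' @param bands a [band_exclusion()].
#' @return a [compute_psa()] result.
#' @export
psa_of_trace <- function(trace, bands = band_exclusion()) {
  compute_psa(apply_exclusions(periodogram(trace), bands))
}

#' Export a power spectrum as a CSV table
#'
#' @param spectrum a [power_spectrum].
#' @param path output CSV path (`freq_hz,psd_pa2_per_hz,retained`).
#' @return the path, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(data.frame(freq_hz = spectrum$freqs,
                              psd_pa2_per_hz = spectrum$psd,
                              retained = spectrum$mask),
                   path, row.names = FALSE)
  invisible(path)
}
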