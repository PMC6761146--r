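#' Markov gating scheme
#'
#' A continuous-time Markov chain over channel states, each carrying a
#' conductance. Exactly one state must have conductance 0 (the closed state);
#' all other states conduct (full open or substates). The rate matrix holds
#' transition rates in s^-1; its diagonal is forced to minus the row sum so
#' the rows describe a proper CTMC generator.
#'
#' @param labels character vector of state names.
#' @param conductances_ps conductance of each state (pS), >= 0, exactly one 0.
#' @param rates square matrix of transition rates (s^-1), off-diagonal >= 0.
#'   The diagonal is recomputed.
#' @param flicker_states optional character vector flagging brief-lived
#'   states (documentation only; does not change the kinetics).
#' @return an object of class `gating_scheme`.
#' @export
gating_scheme <- function(labels, conductances_ps, rates,
                          flicker_states = character(0)) {
  n <- length(labels)
  stopifnot(length(conductances_ps) == n, is.matrix(rates),
            nrow(rates) == n, ncol(rates) == n)
  off <- rates; diag(off) <- 0
  if (any(off < 0)) stop("parameter error: off-diagonal rates must be >= 0")
  if (any(conductances_ps < 0)) stop("conductances must be >= 0")
  if (sum(conductances_ps == 0) != 1) {
    stop("exactly one state must have conductance 0 (the closed state)")
  }
  diag(off) <- -rowSums(off)
  dimnames(off) <- list(labels, labels)
  structure(list(labels = labels, conductances_ps = conductances_ps,
                 rates = off, flicker_states = flicker_states),
            class = "gating_scheme")
}

#' Two-state (closed/open) gating scheme
#'
#' @param g_open_ps open-state conductance (pS).
#' @param k_open closed-to-open rate (s^-1).
#' @param k_close open-to-closed rate (s^-1).
#' @return a [gating_scheme()].
#' @export
two_state_scheme <- function(g_open_ps, k_open, k_close) {
  gating_scheme(c("closed", "open"), c(0, g_open_ps),
                matrix(c(0, k_open, k_close, 0), 2, 2, byrow = TRUE))
}

#' Default multi-substate gating scheme
#'
#' Closed (0 pS) <-> substate (300 pS, the most frequent subconductance
#' level) <-> full open (1300 pS, the megachannel's maximal conductance),
#' plus a brief flicker substate (600 pS, ~2 ms mean dwell) branching off
#' the substate. Rates give a stationary occupancy of roughly 2/3 closed,
#' 22% substate, 11% full open, with full-open dwells of 25 ms on average,
#' so stable (>= 10 ms) top-level events are plentiful in a 60 s record.
#'
#' @param g_sub_ps substate conductance (pS).
#' @param g_open_ps full-open conductance (pS).
#' @param g_flicker_ps flicker-substate conductance (pS).
#' @return a [gating_scheme()].
#' @export
multistate_scheme <- function(g_sub_ps = 300, g_open_ps = 1300,
                              g_flicker_ps = 600) {
  labels <- c("closed", "sub", "open", "flicker")
  rates <- matrix(0, 4, 4, dimnames = list(labels, labels))
  rates["closed", "sub"] <- 5
  rates["sub", "closed"] <- 15
  rates["sub", "open"] <- 20
  rates["open", "sub"] <- 40
  rates["sub", "flicker"] <- 10
  rates["flicker", "sub"] <- 500
  gating_scheme(labels, c(0, g_sub_ps, g_open_ps, g_flicker_ps), rates,
                flicker_states = "flicker")
}

#' Ca2+ activation parameters
#'
#' Ground-truth dose-response of the simulator: the stationary open
#' probability follows a Hill curve in Ca2+, realized kinetically through the
#' closed-state exit rate at a fixed closing rate.
#'
#' @param n_hill Hill coefficient (> 0).
#' @param k_half half-activation Ca2+ (mM, > 0).
#' @param po_max asymptotic open probability at saturating Ca2+ (0 < po <= 1).
#' @param k_close closing rate (s^-1, > 0).
#' @return an object of class `ca_activation`.
#' @export
ca_activation <- function(n_hill, k_half, po_max, k_close) {
  stopifnot(n_hill > 0, k_half > 0, po_max > 0, po_max <= 1, k_close > 0)
  structure(list(n_hill = n_hill, k_half = k_half, po_max = po_max,
                 k_close = k_close), class = "ca_activation")
}

#' Stationary open probability at a given Ca2+ concentration
#'
#' Evaluates the Hill curve
#' `po_max * ca^n / (k_half^n + ca^n)`: 0 at ca = 0, approaching po_max at
#' saturating ca, strictly increasing in between.
#'
#' @param activation a [ca_activation()].
#' @param ca_mm Ca2+ concentration (mM, >= 0); vectorized.
#' @return open probability in \[0, po_max).
#' @export
stationary_po <- function(activation, ca_mm) {
  stopifnot(all(ca_mm >= 0))
  r <- (ca_mm / activation$k_half)^activation$n_hill
  activation$po_max * r / (1 + r)
}

#' Apply Ca2+ modulation to a gating scheme
#'
#' Rescales the closed-state exit rates so that their sum equals
#' `k_close * p / (1 - p)` with `p = stationary_po(activation, ca_mm)`. For a
#' two-state scheme whose closing rate is `k_close` the chain's stationary
#' open occupancy then equals `p` exactly; for multi-state schemes the
#' closed-to-conducting aggregate rate is set the same way and all other
#' rates are left untouched. At ca = 0 the opening rate is 0 and the channel
#' never leaves the closed state.
#'
#' @param scheme a [gating_scheme()].
#' @param activation a [ca_activation()].
#' @param ca_mm Ca2+ concentration (mM).
#' @return a modified [gating_scheme()].
#' @export
ca_modulated_rates <- function(scheme, activation, ca_mm) {
  p <- stationary_po(activation, ca_mm)
  if (p >= 1) {
    stop("parameter error: stationary po = 1 gives an infinite opening rate;",
         " use po_max < 1 or finite ca")
  }
  k_open <- activation$k_close * p / (1 - p)
  ci <- which(scheme$conductances_ps == 0)
  row <- scheme$rates[ci, ]
  row[ci] <- 0
  tot <- sum(row)
  if (tot > 0) {
    row <- row * (k_open / tot)
  } else {
    # closed state has no outgoing pathway in the template: open towards the
    # lowest-conductance conducting state
    target <- which(scheme$conductances_ps > 0)
    target <- target[which.min(scheme$conductances_ps[target])]
    row[target] <- k_open
  }
  rates <- scheme$rates
  rates[ci, ] <- row
  gating_scheme(scheme$labels, scheme$conductances_ps, rates,
                scheme$flicker_states)
}

#' Acquisition noise model
#'
#' Additive disturbances of the recording chain: Gaussian instrument noise
#' (specified as the SD observed after the low-pass filter), a mains-line
#' sinusoid, slow baseline drift realized as a first-order Gauss-Markov
#' (Ornstein-Uhlenbeck) process whose corner sits below the 2 Hz analysis
#' exclusion, and a constant current offset such as the one imposed by an
#' ionic gradient.
#'
#' @param sigma_white Gaussian noise SD after filtering (pA).
#' @param line_amp line-interference amplitude (pA).
#' @param line_freq line frequency (Hz).
#' @param drift_amp stationary SD of the baseline drift (pA).
#' @param drift_corner drift bandwidth (Hz); keep below 2 Hz so the
#'   analysis exclusion band removes it.
#' @param offset_pa constant current offset (pA).
#' @param seed default RNG seed used when rendering with this model.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(sigma_white = 1.5, line_amp = 1, line_freq = 50,
                        drift_amp = 0.5, drift_corner = 0.5, offset_pa = 0,
                        seed = 1L) {
  stopifnot(sigma_white >= 0, line_amp >= 0, drift_amp >= 0,
            drift_corner > 0)
  structure(list(sigma_white = sigma_white, line_amp = line_amp,
                 line_freq = line_freq, drift_amp = drift_amp,
                 drift_corner = drift_corner, offset_pa = offset_pa,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Simulation scenario
#'
#' Composes gating, Ca2+ activation, noise, holding potential and the
#' acquisition parameters (10 kHz sampling, 500 Hz low-pass by default) into
#' one simulated-experiment description.
#'
#' @param gating a [gating_scheme()].
#' @param noise a [noise_model()].
#' @param v_cis holding potential (mV).
#' @param duration recording length (s, > 0).
#' @param activation optional [ca_activation()]; when present,
#'   [simulate_trace()] modulates the closed-state exit rate by the
#'   condition's Ca2+ concentration.
#' @param sampling_rate sampling rate (Hz).
#' @param filter_cutoff low-pass corner (Hz); must be < sampling_rate/2.
#' @param condition a [condition_label()].
#' @return an object of class `sim_scenario`.
#' @export
sim_scenario <- function(gating, noise, v_cis, duration,
                         activation = NULL, sampling_rate = 10000,
                         filter_cutoff = 500,
                         condition = condition_label()) {
  stopifnot(duration > 0)
  if (sampling_rate < 2 * filter_cutoff) {
    stop("aliasing error: sampling_rate must be >= 2 * filter_cutoff")
  }
  structure(list(gating = gating, noise = noise, v_cis = v_cis,
                 duration = duration, activation = activation,
                 sampling_rate = sampling_rate,
                 filter_cutoff = filter_cutoff, condition = condition),
            class = "sim_scenario")
}

#' Simulate a gating trajectory (Gillespie)
#'
#' Draws a continuous-time Markov trajectory from a gating scheme: dwell
#' times are exponential with each state's total exit rate, and the successor
#' state is drawn proportionally to the outgoing rates. A state with zero
#' exit rate is absorbing (the trajectory stays for the remaining duration).
#'
#' @param scheme a [gating_scheme()].
#' @param duration trajectory length (s, > 0).
#' @param seed RNG seed; the trajectory is reproducible given (scheme, seed).
#' @param init initial state index; defaults to the closed state.
#' @return a data.frame with columns `state` (index), `dwell` (s) covering
#'   `[0, duration]`, with the scheme attached as attribute `scheme`.
#' @export
simulate_path <- function(scheme, duration, seed = 1L, init = NULL) {
  stopifnot(duration > 0)
  if (is.null(init)) init <- which(scheme$conductances_ps == 0)
  exit <- -diag(scheme$rates)
  n <- nrow(scheme$rates)
  with_seed(seed, {
    states <- integer(0); dwells <- numeric(0)
    s <- init; t <- 0
    while (t < duration) {
      rate <- exit[s]
      if (rate <= 0) { # absorbing
        states <- c(states, s); dwells <- c(dwells, duration - t)
        t <- duration
        break
      }
      d <- stats::rexp(1, rate)
      d <- min(d, duration - t)
      states <- c(states, s); dwells <- c(dwells, d)
      t <- t + d
      if (t >= duration) break
      pr <- scheme$rates[s, ]; pr[s] <- 0
      s <- sample.int(n, 1, prob = pr)
    }
    out <- data.frame(state = states, dwell = dwells)
    attr(out, "scheme") <- scheme
    out
  })
}

# post-filter/pre-filter white-noise SD ratio of the digital Butterworth
filter_gain_ratio <- function(filt, n = 4096) {
  h <- signal::freqz(filt$b, filt$a, n = n)
  sqrt(mean(Mod(h$h)^2))
}

#' Render a gating trajectory into a current trace
#'
#' Applies the acquisition chain: the ideal current of each sample is
#' `conductance(state) * v_cis / 1000` (pS * mV -> pA, sign following
#' v_cis), plus the constant offset, line sinusoid, Ornstein-Uhlenbeck drift
#' and white Gaussian noise; the composite is low-pass filtered with a
#' causal 4-pole Butterworth at the scenario's cutoff (the analog filter's
#' named corner; the topology is a package convention) and sampled at the
#' scenario's rate. The white-noise SD is scaled before filtering so that
#' the post-filter SD equals the model's `sigma_white`. A short pre-roll at
#' the initial level is filtered and discarded so the output starts settled.
#'
#' @param path trajectory from [simulate_path()] (must cover the duration).
#' @param scenario a [sim_scenario()].
#' @param seed RNG seed for the noise; defaults to the noise model's seed.
#'   Output is bit-reproducible given (path, scenario, seed).
#' @return a [current_trace()].
#' @export
render_trace <- function(path, scenario, seed = NULL) {
  if (is.null(seed)) seed <- scenario$noise$seed
  scheme <- attr(path, "scheme")
  if (is.null(scheme)) scheme <- scenario$gating
  fs <- scenario$sampling_rate
  fc <- scenario$filter_cutoff
  if (fs < 2 * fc) stop("aliasing error: sampling_rate < 2 * filter_cutoff")
  n <- round(scenario$duration * fs)
  if (sum(path$dwell) < scenario$duration - 1e-9) {
    stop("trajectory does not cover the scenario duration")
  }
  dt <- 1 / fs
  t_mid <- (seq_len(n) - 0.5) * dt
  ends <- cumsum(path$dwell)
  idx <- findInterval(t_mid, c(0, ends[-length(ends)]))
  g <- scheme$conductances_ps[path$state[idx]]
  ideal <- g * scenario$v_cis / 1000
  nm <- scenario$noise
  pad <- round(0.05 * fs)
  x <- c(rep(ideal[1], pad), ideal) + nm$offset_pa
  t_all <- (seq_len(n + pad) - pad - 0.5) * dt
  if (nm$line_amp > 0) {
    x <- x + nm$line_amp * sin(2 * pi * nm$line_freq * t_all)
  }
  with_seed(seed, {
    if (nm$drift_amp > 0) {
      a <- exp(-2 * pi * nm$drift_corner * dt)
      z <- stats::rnorm(n + pad, sd = nm$drift_amp * sqrt(1 - a^2))
      x0 <- stats::rnorm(1, sd = nm$drift_amp)
      x <- x + as.numeric(stats::filter(z, a, method = "recursive",
                                        init = x0))
    }
    if (nm$sigma_white > 0) {
      filt <- signal::butter(4, fc / (fs / 2), type = "low")
      sd_pre <- nm$sigma_white / filter_gain_ratio(filt)
      x <- x + stats::rnorm(n + pad, sd = sd_pre)
    }
  })
  filt <- signal::butter(4, fc / (fs / 2), type = "low")
  y <- signal::filter(filt, x)
  y <- as.numeric(y)[(pad + 1):(pad + n)]
  current_trace(y, sampling_rate = fs, v_cis = scenario$v_cis,
                condition = scenario$condition, filter_cutoff = fc,
                offset_note = if (nm$offset_pa != 0) nm$offset_pa else NA_real_)
}

#' Simulate one complete recording from a scenario
#'
#' Convenience composition: when the scenario carries a [ca_activation()],
#' the gating scheme's opening rate is modulated by the condition's Ca2+
#' concentration, then a trajectory is drawn and rendered. Path and noise
#' seeds are derived deterministically from `seed`.
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer seed.
#' @return a [current_trace()].
#' @export
simulate_trace <- function(scenario, seed = 1L) {
  scheme <- scenario$gating
  if (!is.null(scenario$activation)) {
    scheme <- ca_modulated_rates(scheme, scenario$activation,
                                 scenario$condition$ca_mm)
  }
  path <- simulate_path(scheme, scenario$duration,
                        seed = derive_seed(seed, 1))
  render_trace(path, scenario, seed = derive_seed(seed, 2))
}

#' Simulate an inhibitor-addition episode
#'
#' Channel block by inhibitors (Ba2+, Mg-ADP, Gd3+, EGTA) is modelled
#' phenomenologically as a step change of the closed-state exit rate at the
#' addition time: the recording runs under the scenario's gating until
#' `t_add`, then under the same scheme with every closed-state exit rate
#' multiplied by `rate_factor` (0 = full block). No new kinetic states are
#' invented; the model is just sufficient to test episode-wise metric
#' changes.
#'
#' @param scenario a [sim_scenario()].
#' @param t_add inhibitor addition time (s), inside the recording.
#' @param rate_factor multiplier (>= 0) applied to the opening rate after
#'   `t_add`.
#' @param seed integer seed.
#' @return a [current_trace()] covering the full duration, with the
#'   scenario's condition.
#' @export
simulate_inhibition <- function(scenario, t_add, rate_factor, seed = 1L) {
  stopifnot(t_add > 0, t_add < scenario$duration, rate_factor >= 0)
  scheme <- scenario$gating
  if (!is.null(scenario$activation)) {
    scheme <- ca_modulated_rates(scheme, scenario$activation,
                                 scenario$condition$ca_mm)
  }
  ci <- which(scheme$conductances_ps == 0)
  rates2 <- scheme$rates
  rates2[ci, ] <- rates2[ci, ] * rate_factor
  scheme2 <- gating_scheme(scheme$labels, scheme$conductances_ps, rates2,
                           scheme$flicker_states)
  p1 <- simulate_path(scheme, t_add, seed = derive_seed(seed, 1))
  # resume after the addition from the closed state (block interrupts
  # openings on the seconds scale of solution mixing)
  p2 <- simulate_path(scheme2, scenario$duration - t_add,
                      seed = derive_seed(seed, 2), init = ci)
  path <- rbind(p1, p2)
  attr(path, "scheme") <- scheme
  render_trace(path, scenario, seed = derive_seed(seed, 3))
}

#' Simulate a Ca2+ titration series
#'
#' Renders `replicates` recordings at each concentration of an ascending
#' Ca2+ list, modulating the scenario's gating through its activation.
#' Per-trace seeds are derived deterministically from (seed, concentration
#' index, replicate index), so any two traces differ and the whole set is
#' reproducible.
#'
#' @param scenario template [sim_scenario()] (must carry an activation).
#' @param ca_list ascending Ca2+ concentrations (mM), non-empty.
#' @param replicates recordings per concentration (>= 1), either a single
#'   count or one count per concentration.
#' @param seed integer master seed.
#' @return a list of [current_trace()] objects, each with its condition's
#'   `ca_mm` set.
#' @export
simulate_titration <- function(scenario, ca_list, replicates, seed = 1L) {
  if (!length(ca_list)) stop("parameter error: ca_list must be non-empty")
  if (is.unsorted(ca_list, strictly = TRUE)) {
    stop("parameter error: ca_list must be ascending")
  }
  if (length(replicates) == 1) replicates <- rep(replicates, length(ca_list))
  if (any(replicates < 1)) stop("parameter error: replicates must be >= 1")
  if (is.null(scenario$activation)) {
    stop("parameter error: titration scenario needs a ca_activation")
  }
  out <- list()
  for (i in seq_along(ca_list)) {
    for (r in seq_len(replicates[i])) {
      sc <- scenario
      sc$condition$ca_mm <- ca_list[i]
      out[[length(out) + 1L]] <-
        simulate_trace(sc, seed = derive_seed(seed, i, r))
    }
  }
  out
}
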