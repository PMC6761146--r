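# Programmatic fixtures shared across test files. Everything is generated
# in code; no binary data ships with the package.

fs_default <- 10000

# noise-free square wave alternating closed (0 pA) and open (level_pa),
# starting closed; n_cycles full closed+open cycles
square_trace <- function(level_pa = -30, half_ms = 50, n_cycles = 10,
                         v_cis = -60, fs = fs_default) {
  half <- round(half_ms / 1000 * fs)
  x <- rep(c(rep(0, half), rep(level_pa, half)), n_cycles)
  current_trace(x, fs, v_cis = v_cis)
}

# noise-free piecewise-constant trace from (level_pa, duration_ms) pairs
levels_trace <- function(levels_pa, durations_ms, v_cis = -60,
                         fs = fs_default) {
  x <- unlist(mapply(function(l, d) rep(l, round(d / 1000 * fs)),
                     levels_pa, durations_ms, SIMPLIFY = FALSE))
  current_trace(x, fs, v_cis = v_cis)
}

# iid mixture telegraph with Gaussian noise (for baseline / histogram tests;
# no Markov correlation needed there)
mixture_trace <- function(levels_pa, probs, n = 60000, sigma = 1,
                          v_cis = -60, seed = 1, fs = fs_default) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    lev <- sample(levels_pa, n, replace = TRUE, prob = probs)
    current_trace(lev + rnorm(n, sd = sigma), fs, v_cis = v_cis)
  })
}

# the dwell-rule worked example: stable -30 pA openings (50 ms) interleaved
# with 2 ms flicker excursions at -60 pA, rendered through the 500 Hz
# acquisition chain, noise-free, at -60 mV
dwell_rule_trace <- function() {
  sch <- gating_scheme(c("closed", "open", "flicker"), c(0, 500, 1000),
                       matrix(0, 3, 3))
  st <- integer(0); dw <- numeric(0)
  for (k in 1:8) {
    st <- c(st, 1L, 2L, 1L, 3L)
    dw <- c(dw, 0.05, 0.05, 0.05, 0.002)
  }
  st <- c(st, 1L); dw <- c(dw, 0.05)
  path <- data.frame(state = st, dwell = dw)
  attr(path, "scheme") <- sch
  sc <- sim_scenario(sch, noise_model(sigma_white = 0, line_amp = 0,
                                      drift_amp = 0),
                     v_cis = -60, duration = sum(dw))
  render_trace(path, sc, seed = 1)
}

# two-state scenario with a fixed stationary open probability (no Ca
# modulation), for conductance-recovery simulations
fixed_po_scenario <- function(g_open_ps, po, k_close = 50, duration_s = 60,
                              v_cis = -60, sigma_white = 1.5, line_amp = 1,
                              drift_amp = 0.3) {
  sim_scenario(two_state_scheme(g_open_ps, k_open = k_close * po / (1 - po),
                                k_close = k_close),
               noise_model(sigma_white = sigma_white, line_amp = line_amp,
                           drift_amp = drift_amp),
               v_cis = v_cis, duration = duration_s)
}

# 23-recording titration design: 6 Ca2+ concentrations spanning 0.1-3 mM
titration_design <- function() {
  list(ca = c(0.1, 0.25, 0.5, 1, 2, 3), reps = c(4, 4, 4, 4, 4, 3))
}

# per-trace PSA and Po of a titration (light path: only what the Hill fit
# consumes), aggregated to mean +/- SEM per concentration
titration_tables <- function(n_gen, meta_seed, duration_s = 60) {
  des <- titration_design()
  sc <- scenario_titration(n_hill = n_gen, duration_s = duration_s)
  traces <- simulate_titration(sc, des$ca, des$reps, seed = meta_seed)
  bands <- band_exclusion()
  rows <- lapply(traces, function(tr) {
    id <- idealize(tr, k_sigma = 3)
    data.frame(ca_mm = tr$condition$ca_mm,
               psa_pa2 = psa_of_trace(tr, bands)$psa,
               po = compute_po(id))
  })
  metrics <- do.call(rbind, rows)
  list(psa = titration_table(metrics, "psa_pa2"),
       po = titration_table(metrics, "po"))
}

# brute-force permutation oracle for the two-sided exact Mann-Whitney p.
# Independent route: U is recomputed by direct pairwise comparison (number
# of (a_i, b_j) pairs with a_i > b_j, ties counting 1/2), and the null
# distribution by enumerating every assignment of pooled values to groups.
mw_pairwise_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

mw_enumeration_oracle <- function(a, b) {
  n1 <- length(a); N <- n1 + length(b)
  pool <- c(a, b)
  u_obs <- mw_pairwise_u(a, b)
  combs <- utils::combn(N, n1)
  us <- apply(combs, 2, function(ix) mw_pairwise_u(pool[ix], pool[-ix]))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}
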