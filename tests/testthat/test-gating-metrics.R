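test_that("baseline and noise sigma recover their generating values", {
  # pure Gaussian noise: baseline ~ 0, sigma ~ 1 on every seed
  for (s in 1:20) {
    set.seed(s)
    tr <- current_trace(rnorm(20000), 10000)
    bl <- estimate_baseline(tr)
    expect_lt(abs(bl$baseline), 0.05)
    expect_lt(abs(bl$noise_sigma - 1), 0.1)
  }

  # telegraph with a minority open level: the baseline is the dominant
  # closed peak, not the open level and not the overall mean
  tr <- mixture_trace(c(0, -30), c(0.7, 0.3), sigma = 1, seed = 3)
  bl <- estimate_baseline(tr)
  expect_lt(abs(bl$baseline), 0.1)
  expect_lt(abs(bl$noise_sigma - 1), 0.15)

  # shift equivariance
  tr9 <- tr
  tr9$samples <- tr$samples - 9
  expect_equal(estimate_baseline(tr9)$baseline, bl$baseline - 9,
               tolerance = 0.02)

  # a record that never visits 0 pA has no baseline
  far <- current_trace(rnorm(5000, mean = -30), 10000)
  expect_error(estimate_baseline(far), "baseline-not-found")

  expect_error(estimate_baseline(current_trace(rnorm(500), 10000)),
               ">= 1000")
})

test_that("idealization matches constructed epochs and is monotone in k_sigma", {
  sq <- square_trace(level_pa = -30, half_ms = 50, n_cycles = 10)
  id <- idealize(sq, 3)
  expect_identical(id$open_flags, sq$samples != 0)
  expect_identical(nrow(id$events), 10L)
  expect_equal(id$events$mean_pa, rep(-30, 10))
  expect_equal(id$events$n_samples, rep(500L, 10))

  flat <- current_trace(numeric(5000), 10000)
  id0 <- idealize(flat, 3)
  expect_identical(nrow(id0$events), 0L)
  expect_false(any(id0$open_flags))

  # wider noise band never increases open time
  set.seed(4)
  noisy <- mixture_trace(c(0, -8), c(0.6, 0.4), sigma = 2, seed = 9)
  open3 <- sum(idealize(noisy, 3)$open_flags)
  open4 <- sum(idealize(noisy, 4)$open_flags)
  expect_lte(open4, open3)
})

test_that("compute_po counts open time", {
  flat <- current_trace(numeric(5000), 10000)
  expect_equal(compute_po(idealize(flat, 3)), 0)

  sq <- square_trace()
  expect_equal(compute_po(idealize(sq, 3)), 0.5)

  # estimated Po is monotone in the generating stationary Po (paired seeds)
  est <- vapply(c(0.05, 0.15, 0.25, 0.35, 0.45), function(p) {
    sc <- fixed_po_scenario(500, p, k_close = 20, duration_s = 30,
                            sigma_white = 1.5, line_amp = 0, drift_amp = 0)
    compute_po(idealize(simulate_trace(sc, seed = 500), 3))
  }, numeric(1))
  expect_true(all(diff(est) > 0))

  # generating-parameter recovery: slow two-state gating at stationary
  # Po 0.2 (slow switching keeps filter-edge time negligible)
  po_hat <- vapply(1:5, function(s) {
    sc <- fixed_po_scenario(500, po = 0.2, k_close = 4, duration_s = 120,
                            sigma_white = 1, line_amp = 0, drift_amp = 0)
    compute_po(idealize(simulate_trace(sc, seed = 100 + s), 3))
  }, numeric(1))
  se <- stats::sd(po_hat) / sqrt(length(po_hat))
  expect_lt(abs(mean(po_hat) - 0.2), 3 * se + 0.01)
})

test_that("g_mean applies Ohm's law over the open-state signal", {
  sq <- square_trace(level_pa = -30)
  id <- idealize(sq, 3)
  expect_equal(compute_g_mean(id, -60), 500)

  # equal time at -30 and -15 pA: mean open current -22.5 pA -> 375 pS
  mix <- levels_trace(c(0, -30, 0, -15, 0, -30, 0, -15),
                      rep(50, 8))
  idm <- idealize(mix, 3)
  expect_equal(compute_g_mean(idm, -60), 375)

  # Ohmic scale invariance: double the voltage and the currents
  mix2 <- mix
  mix2$samples <- 2 * mix$samples
  expect_equal(compute_g_mean(idealize(mix2, 3), -120), 375)

  expect_error(compute_g_mean(id, 0), "v_cis")
  flat <- current_trace(numeric(5000), 10000)
  expect_true(is.na(compute_g_mean(idealize(flat, 3), -60)))
})

test_that("g_max applies the 10 ms stability rule", {
  # stable -30 pA events (50 ms) with -60 pA flickers (2 ms): flickers are
  # rejected by the dwell rule, admitted when it is lifted
  tr <- levels_trace(c(0, -30, 0, -60, 0, -30, 0, -60, 0),
                     c(50, 50, 50, 2, 50, 50, 50, 2, 50))
  id <- idealize(tr, 3)
  expect_equal(compute_g_max(id, -60, min_dwell_ms = 10), 500)
  expect_equal(compute_g_max(id, -60, min_dwell_ms = 0), 1000)

  # a single 11 ms event at -78 pA reaches 1300 pS
  tr2 <- levels_trace(c(0, -78, 0), c(50, 11, 50))
  expect_equal(compute_g_max(idealize(tr2, 3), -60, 10), 1300)

  # boundary: an event of exactly min_dwell qualifies, one sample shorter
  # does not
  fs <- 10000
  exact <- levels_trace(c(0, -50, 0, -30, 0), c(50, 10, 50, 50, 50), fs = fs)
  expect_equal(compute_g_max(idealize(exact, 3), -60, 10), 50 / 60 * 1000)
  short <- current_trace(
    c(rep(0, 500), rep(-50, 99), rep(0, 500), rep(-30, 500), rep(0, 500)),
    fs, v_cis = -60)
  expect_equal(compute_g_max(idealize(short, 3), -60, 10), 500)

  expect_error(compute_g_max(id, 0), "v_cis")
  flick_only <- levels_trace(c(0, -60, 0), c(100, 2, 100))
  expect_true(is.na(compute_g_max(idealize(flick_only, 3), -60, 10)))
})

test_that("amplitude histogram resolves the conducting levels as peaks", {
  # noise only: exactly one peak, at ~0 pA
  set.seed(12)
  noise <- current_trace(rnorm(60000), 10000)
  h1 <- amplitude_histogram(noise, bin_width = 1)
  expect_identical(nrow(h1$peaks), 1L)
  expect_lt(abs(h1$peaks$level_pa[1]), 1)
  expect_equal(sum(h1$counts), 60000)

  # three levels (closed, substate, full open at -80 mV)
  tr3 <- mixture_trace(c(0, -18, -104), c(0.55, 0.25, 0.2), n = 60000,
                       sigma = 1, v_cis = -80, seed = 5)
  h3 <- amplitude_histogram(tr3, bin_width = 1)
  expect_identical(nrow(h3$peaks), 3L)
  expect_equal(h3$peaks$level_pa, c(0, -18, -104), tolerance = 1)

  # peak count is stable when the bin width is halved
  h3b <- amplitude_histogram(tr3, bin_width = 0.5)
  expect_identical(nrow(h3b$peaks), 3L)
})

test_that("analyze_trace composes the estimators and is deterministic", {
  cfg <- default_config()

  # noise-only trace: tiny Po, absent conductances, PSA near the noise floor
  set.seed(30)
  w <- current_trace(rnorm(60000, sd = 1.5), 10000, v_cis = -60)
  m <- analyze_trace(w, cfg)
  expect_lt(m$po, 0.02)
  expect_true(is.na(m$g_mean_ps) || m$po > 0)
  sigma_floor <- 1.5^2 * (2 * 498 / 10000) # flat spectrum share of the band
  expect_equal(m$psa_pa2, sigma_floor, tolerance = 0.5)

  # determinism
  m2 <- analyze_trace(w, cfg)
  expect_identical(as.data.frame(m), as.data.frame(m2))

  # complex multi-substate recording: top level ~1300 pS, several peaks
  tr <- simulate_trace(scenario_multistate(duration_s = 20), seed = 77)
  mm <- analyze_trace(tr, cfg)
  expect_equal(mm$g_max_ps, 1300, tolerance = 0.05)
  hist <- attr(mm, "histogram")
  expect_gte(nrow(hist$peaks), 3)
  expect_gt(mm$po, 0.1)
})

test_that("conductances are voltage- and baseline-shift equivariant", {
  # identical gating path rendered at two holding potentials
  sch <- multistate_scheme()
  path <- simulate_path(sch, 20, seed = 50)
  quietish <- noise_model(sigma_white = 1.5, line_amp = 0, drift_amp = 0)
  g <- vapply(c(-60, -80), function(v) {
    sc <- sim_scenario(sch, quietish, v_cis = v, duration = 20)
    tr <- render_trace(path, sc, seed = 51)
    id <- idealize(tr, 3)
    c(compute_g_mean(id, v), compute_g_max(id, v, 10))
  }, numeric(2))
  expect_equal(g[1, 1], g[1, 2], tolerance = 0.03)
  expect_equal(g[2, 1], g[2, 2], tolerance = 0.03)

  # adding a constant to a noise-free record shifts the baseline only
  sq <- square_trace()
  id0 <- idealize(sq, 3)
  sq7 <- sq
  sq7$samples <- sq$samples + 7
  id7 <- idealize(sq7, 3)
  expect_equal(id7$baseline, id0$baseline + 7)
  expect_identical(compute_po(id7), compute_po(id0))
  expect_identical(compute_g_mean(id7, -60), compute_g_mean(id0, -60))
  expect_identical(compute_g_max(id7, -60, 10), compute_g_max(id0, -60, 10))

  # conductance ordering on a multi-level record
  tr <- simulate_trace(scenario_multistate(duration_s = 20), seed = 88)
  id <- idealize(tr, 3)
  expect_gte(compute_g_max(id, -80, 10), compute_g_mean(id, -80))
})
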