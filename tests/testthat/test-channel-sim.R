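test_that("stationary_po follows the Hill dose-response", {
  act <- ca_activation(n_hill = 1, k_half = 1, po_max = 1, k_close = 100)
  expect_equal(stationary_po(act, 1), 0.5)
  expect_equal(stationary_po(act, 0), 0)

  act2 <- ca_activation(2, 0.5, 0.8, 100)
  expect_equal(stationary_po(act2, 0.5), 0.4)

  # strictly increasing, saturating at po_max
  ca <- c(0.01, 0.1, 0.5, 1, 5, 50, 5000)
  po <- stationary_po(act2, ca)
  expect_true(all(diff(po) > 0))
  expect_lt(po[length(po)], 0.8)
  expect_equal(stationary_po(act2, 1e9), 0.8, tolerance = 1e-6)
})

test_that("ca_modulated_rates targets the stationary occupancy", {
  sch <- two_state_scheme(500, k_open = 0, k_close = 100)
  act <- ca_activation(1, 1, po_max = 1 - 1e-12, k_close = 100)

  # p = 0.5 -> opening rate equals the closing rate (symmetry)
  m <- ca_modulated_rates(sch, ca_activation(1, 1, 0.5000000001, 100), 1e12)
  expect_equal(m$rates["closed", "open"], 100, tolerance = 1e-3)

  # p = 0.2 -> opening rate k_close * 0.25
  act2 <- ca_activation(1, 1, 0.4, 100)
  m2 <- ca_modulated_rates(sch, act2, 1) # p = 0.2
  expect_equal(m2$rates["closed", "open"], 25)

  # ca = 0: never leaves the closed state
  m0 <- ca_modulated_rates(sch, act2, 0)
  expect_equal(m0$rates["closed", "open"], 0)
  path0 <- simulate_path(m0, 5, seed = 3)
  expect_identical(nrow(path0), 1L)
  expect_equal(path0$dwell, 5)

  # po_max = 1 at saturating ca is rejected (infinite opening rate)
  expect_error(
    ca_modulated_rates(sch, ca_activation(1, 1e-9, 1, 100), 1e9),
    "po")

  # long-run occupancy of the conducting state matches the target
  occ <- function(path) {
    open <- attr(path, "scheme")$conductances_ps[path$state] > 0
    sum(path$dwell[open]) / sum(path$dwell)
  }
  p_target <- 0.2
  path <- simulate_path(ca_modulated_rates(sch, act2, 1), 100, seed = 42)
  n_dwells <- nrow(path)
  se <- sqrt(p_target * (1 - p_target) / n_dwells) * 2 # conservative scale
  expect_lt(abs(occ(path) - p_target), 3 * se + 0.01)
})

test_that("simulate_path draws exponential dwells reproducibly", {
  sch <- two_state_scheme(500, k_open = 10, k_close = 10)

  p1 <- simulate_path(sch, 50, seed = 7)
  p2 <- simulate_path(sch, 50, seed = 7)
  expect_identical(p1, p2)

  long <- simulate_path(sch, 1000, seed = 9)
  closed_dw <- long$dwell[long$state == 1]
  closed_dw <- closed_dw[-length(closed_dw)] # drop possibly truncated last
  expect_equal(mean(closed_dw), 1 / 10,
               tolerance = 5 * 1 / sqrt(length(closed_dw)))

  # dwell distribution is exponential (KS on ~10^4 dwells)
  big <- simulate_path(sch, 1100, seed = 10)
  dw <- big$dwell[big$state == 1]
  dw <- dw[-length(dw)]
  expect_gt(length(dw), 5000)
  expect_gt(stats::ks.test(dw, "pexp", 10)$p.value, 0.01)

  # zero exit rate is absorbing, not an error
  frozen <- gating_scheme(c("c", "o"), c(0, 500), matrix(0, 2, 2))
  pf <- simulate_path(frozen, 3, seed = 1)
  expect_identical(nrow(pf), 1L)
})

test_that("render_trace is Ohmic, settles under the filter, and is bit-reproducible", {
  sch <- two_state_scheme(500, 0, 1)
  quiet <- noise_model(sigma_white = 0, line_amp = 0, drift_amp = 0)

  # closed-only path with zero noise renders to 0 pA everywhere
  scc <- sim_scenario(sch, quiet, v_cis = -60, duration = 1)
  pc <- data.frame(state = 1, dwell = 1)
  attr(pc, "scheme") <- sch
  expect_true(all(render_trace(pc, scc, seed = 1)$samples == 0))

  # permanently open 500 pS at -60 mV settles to -30 pA (Ohm's law)
  po <- data.frame(state = 2, dwell = 1)
  attr(po, "scheme") <- sch
  y <- render_trace(po, scc, seed = 1)$samples
  expect_equal(tail(y, 1), -30, tolerance = 1e-6)
  expect_lt(max(abs(y[5000:10000] + 30)) / 30, 0.01)

  # same seed twice: bit-identical even with every noise source on
  noisy <- sim_scenario(sch, noise_model(2, 1, 50, 0.5, 0.5, 13),
                        v_cis = -60, duration = 2)
  po2 <- data.frame(state = 2, dwell = 2)
  attr(po2, "scheme") <- sch
  t1 <- render_trace(po2, noisy, seed = 5)
  t2 <- render_trace(po2, noisy, seed = 5)
  expect_identical(t1$samples, t2$samples)
  t3 <- render_trace(po2, noisy, seed = 6)
  expect_false(identical(t1$samples, t3$samples))

  # offset is carried into the trace and noted
  expect_equal(t1$offset_note, 13)
  expect_equal(mean(t1$samples[5000:20000]), -30 + 13, tolerance = 0.2)

  # aliasing guard
  expect_error(sim_scenario(sch, quiet, -60, 1, sampling_rate = 800),
               "aliasing")
})

test_that("white-noise SD is calibrated to its post-filter value", {
  sch <- two_state_scheme(500, 0, 1)
  sc <- sim_scenario(sch, noise_model(sigma_white = 2, line_amp = 0,
                                      drift_amp = 0),
                     v_cis = -60, duration = 30)
  p <- data.frame(state = 1, dwell = 30)
  attr(p, "scheme") <- sch
  y <- render_trace(p, sc, seed = 21)$samples
  expect_equal(stats::sd(y), 2, tolerance = 0.03)
})

test_that("an inhibitor episode suppresses activity after the addition time", {
  sc <- fixed_po_scenario(500, po = 0.4, k_close = 20, duration_s = 20,
                          sigma_white = 1, line_amp = 0, drift_amp = 0)
  tr <- simulate_inhibition(sc, t_add = 10, rate_factor = 0, seed = 3)
  expect_length(tr$samples, 20 * 10000)
  id <- idealize(tr, 3)
  fs <- tr$sampling_rate
  po_before <- mean(id$open_flags[1:(10 * fs)])
  po_after <- mean(id$open_flags[(12 * fs):(20 * fs)]) # margin past mixing
  expect_gt(po_before, 0.2)
  expect_lt(po_after, 0.01)

  # deterministic and guarded
  tr2 <- simulate_inhibition(sc, t_add = 10, rate_factor = 0, seed = 3)
  expect_identical(tr$samples, tr2$samples)
  expect_error(simulate_inhibition(sc, t_add = 25, rate_factor = 0), "t_add")
})

test_that("simulate_titration derives distinct seeds and tracks the dose-response", {
  sc <- scenario_titration(n_hill = 1.17, duration_s = 2)

  traces <- simulate_titration(sc, c(0.5, 2), replicates = 2, seed = 31)
  expect_length(traces, 4)
  expect_false(identical(traces[[1]]$samples, traces[[2]]$samples))
  again <- simulate_titration(sc, c(0.5, 2), replicates = 2, seed = 31)
  expect_identical(traces[[1]]$samples, again[[1]]$samples)
  expect_equal(traces[[3]]$condition$ca_mm, 2)

  expect_error(simulate_titration(sc, c(2, 0.5), 2, 1), "ascending")
  expect_error(simulate_titration(sc, c(0.5), 0, 1), "replicates")
  expect_error(simulate_titration(sc, numeric(0), 2, 1), "non-empty")

  # at ca = 0 the channel never opens: the noise-free rendering is flat zero
  sc0 <- scenario_titration(n_hill = 1.17, duration_s = 2, sigma_white = 0)
  sc0$noise$line_amp <- 0; sc0$noise$drift_amp <- 0
  tr0 <- simulate_titration(sc0, 0, replicates = 1, seed = 1)[[1]]
  expect_true(all(tr0$samples == 0))

  # occupancy of the conducting state increases with ca (path level,
  # long duration so sampling error cannot reorder the grid)
  act <- sc$activation
  occ <- vapply(c(0.2, 0.6, 1.5, 3), function(ca) {
    sch <- ca_modulated_rates(sc$gating, act, ca)
    path <- simulate_path(sch, 150, seed = 7 + round(ca * 10))
    open <- attr(path, "scheme")$conductances_ps[path$state] > 0
    sum(path$dwell[open]) / sum(path$dwell)
  }, numeric(1))
  expect_true(all(diff(occ) > 0))
  expect_equal(occ, stationary_po(act, c(0.2, 0.6, 1.5, 3)), tolerance = 0.25)
})
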