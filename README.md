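# bilayerPSA

Single-channel current analysis for planar lipid bilayer recordings of
Ca²⁺-activated, high-conductance channels (the mitochondrial
megachannel / permeability transition pore regime), plus a synthetic
recording generator that emulates the full acquisition chain so the whole
pipeline is testable without experimental data.

## Who this is for

Bilayer electrophysiologists analysing recordings of flickery,
multi-conductance channels, where classical event statistics struggle, and
method developers who need a reproducible, simulator-backed reference for
such analyses.

## What it computes

Per recording (current in pA, sampled at 10 kHz, low-pass filtered at
500 Hz):

- **PSA** (power spectrum area): the integral of the one-sided power
  spectral density over a retained band, excluding < 2 Hz (baseline
  drift), 50 ± 1 Hz (mains) and > 500 Hz (beyond the filter corner). The
  periodogram is Parseval-normalized, so PSA is a band-limited activity
  variance in pA².
- **Po**: fraction of time the current sits outside a noise band around
  the closed baseline, `|I - baseline| > k_sigma * sigma` (default 3σ).
- **G_mean**: `1000 * |mean open-state current - baseline| / |V_cis|` in
  pS.
- **G_max**: the conductance of the maximal *stable* current level —
  events sustained ≥ 10 ms, measured on stability-gated stretches.
- Amplitude histograms with substate peak detection.

Across recordings: Hill fits
`y = y_max * c^n / (K^n + c^n)` to PSA/Po-versus-[Ca²⁺] titrations
(SEM-weighted, log-space parameters, Levenberg–Marquardt), linear I–V
fits with constant-offset correction (the intercept absorbs a
gradient-imposed current shift), and exact Mann–Whitney group
comparisons.

The simulator draws continuous-time Markov gating over multi-conductance
states (Gillespie), with a Hill-type Ca²⁺ activation of the opening rate,
and renders Ohmic currents through Gaussian noise, 50 Hz line
interference, sub-2 Hz Ornstein–Uhlenbeck drift, a constant offset, and a
causal 4-pole 500 Hz Butterworth at 10 kHz — bit-reproducible per seed.

## Worked example

Simulate the packaged multi-substate scenario (closed / 300 pS substate /
1300 pS full open / brief 600 pS flicker, 60 s at −80 mV, 2 pA noise) and
analyze it:

```r
library(bilayerPSA)
tr <- simulate_trace(scenario_multistate(), seed = 42)
m  <- analyze_trace(tr, default_config())
m[, c("psa_pa2", "po", "g_mean_ps", "g_max_ps", "n_events")]
#>   psa_pa2       po g_mean_ps g_max_ps n_events
#> 1 700.991 0.329942   669.215  1325.95      433
print(attr(m, "histogram"))
#> amplitude_histogram: 131 bins, 3 peaks at -0.5, -24.5, -104 pA
```

Reading: the channel conducts for 33% of the recording (`po`); the
amplitude histogram resolves the closed level, the ~300 pS substate
(−24 pA at −80 mV) and the full-open level (−104 pA); the maximal stable
level corresponds to ~1.33 nS, recovering the simulator's 1.3 nS
full-open conductance within 2%; and the PSA (~700 pA²) summarizes total
activity in one number that is insensitive to flicker and substate
structure.

Fit a Ca²⁺ titration and compare conditions:

```r
traces  <- simulate_titration(scenario_titration(n_hill = 1.17),
                              ca_list = c(0.1, 0.25, 0.5, 1, 2, 3),
                              replicates = c(4, 4, 4, 4, 4, 3), seed = 1)
metrics <- do.call(rbind, lapply(traces, analyze_trace))
hill_fit(titration_table(metrics, "po"))
#> hill_fit: y_max 0.1989, k_half 0.5477 mM, n 1.22 +/- 0.039, R^2 0.9997
#>   (converged, 6 pts, SEM-weighted)
```

The fitted cooperativity (n ≈ 1.22 ± 0.04) recovers the generating Hill
coefficient 1.17; `y_max` and `k_half` recover the scenario's asymptotic
open probability (0.2) and half-activation (0.6 mM).

A shell entry point wrapping the same functions ships in
`inst/exec/bilayer-psa`
(`simulate` / `analyze` / `fit` / `run-all` / `fixtures` subcommands, YAML
config, CSV/JSON outputs).

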