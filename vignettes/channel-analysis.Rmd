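---
title: "Single-channel analysis of Ca2+-activated megachannel recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-channel analysis of Ca2+-activated megachannel recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilayerPSA)
```

## The measurement problem

Planar lipid bilayer recordings of the mitochondrial megachannel (the
Ca2+-activated, high-conductance channel attributed to F-ATP synthase,
also known as the permeability transition pore) are notoriously awkward for
classical single-channel statistics: the channel flickers, visits several
conductance substates below its ~1.3 nS full-open level, and recordings
carry mains interference and slow baseline drift on top of the instrument
noise. `bilayerPSA` implements an analysis chain built for exactly this
regime, together with a simulator of the whole acquisition chain so every
estimator can be exercised against a known ground truth without any
experimental data.

The pipeline computes, per recording:

* **PSA (power spectrum area)** — the integral of the one-sided power
  spectral density of the current over a retained frequency band. Because
  the periodogram is normalized so its full-band integral equals the
  signal's mean-square deviation (discrete Parseval), PSA acts as a
  band-limited activity variance in pA². It is robust to flicker and to
  multiple current levels, which defeat event-based statistics.
* **Po (open probability)** — the fraction of the recording spent outside
  a noise band around the closed-state baseline.
* **G_mean** — the Ohm's-law conductance of the average open-state
  current.
* **G_max** — the conductance of the maximal *stable* current level,
  where stable means sustained for at least 10 ms.

Across recordings, the package fits the Hill equation
\(y = y_\mathrm{max}\, c^{n} / (K^{n} + c^{n})\) to PSA- and
Po-versus-Ca2+ titrations, a straight line (with constant-offset
correction) to current–voltage series, and compares condition groups with
the exact Mann–Whitney test.

## The spectral statistic

The periodogram is a full-record, rectangular-window FFT of the
mean-subtracted current. No Welch averaging is applied: PSA is an integral
statistic whose expectation is window-invariant, and a single long window
keeps the estimator simple and exactly Parseval-consistent. Three bands
are excluded before integration, following standard bilayer practice:

* below 2 Hz — baseline drift;
* within 1 Hz of the 50 Hz mains line — power-line interference (the
  half-width is a package convention; it covers mains wander while
  removing under 0.5% of the retained band);
* above 500 Hz — beyond the analog anti-alias filter corner.

Bound conventions: a bin is dropped when `f < f_low`,
`|f - 50| < line_halfwidth` or `f > f_high`, so the 2 Hz and 500 Hz bins
themselves are retained; the DC bin is always dropped (it is zero after
mean subtraction anyway). Integration is trapezoidal on the FFT grid,
per contiguous retained run — exact for flat spectra and for tones in
interior bins.

## Idealization and the conductance estimators

The closed-state baseline is the dominant amplitude-histogram peak nearest
0 pA; among near-equal peaks the one nearest 0 wins, so a 50%-duty
two-level record resolves to the closed level. The noise SD is obtained by
fitting a Gaussian to that peak's core through iteratively truncated
moments: the SD observed inside a window of half-width \(W\) around the
peak equals \(\sigma\,g(W/\sigma)\) for a Gaussian core, and this relation
is inverted (by root finding) while the window tracks 2.5 fitted SDs. This
stays calibrated where a naive truncated SD underestimates by ~15%.
Noise-free synthetic records degrade to a zero-width peak; the SD is then
floored at \(10^{-6}\) pA so thresholding stays defined.

A sample is *open* when it lies outside `k_sigma` (default 3) noise SDs of
the baseline — at 3 the false-open time is ~0.3% per tail for Gaussian
noise. Events are maximal open runs. Because the causal 4-pole low-pass
smears each transition over ~1 ms and leaves settling tails inside the
threshold band, an event's *level* is estimated as the mean of its samples
within the noise band around the event median: transition samples are
discarded adaptively rather than by a fixed trim, which keeps noise-free
worked examples exact.

`G_max` implements the 10 ms stability rule: only events of at least
`min_dwell_ms` qualify (an event of exactly the threshold duration
qualifies; one sample shorter does not), and within each, 10 ms windows
whose SD exceeds 1.5 noise SDs — windows straddling a level change, a
filter edge or its overshoot — are rejected; surviving consecutive windows
are merged and averaged whole. Averaging whole stable stretches, rather
than maximizing over short windows, suppresses the upward selection bias
that a maximum over many noisy 10 ms means would carry. `G_mean` follows the plainer
reading of "average current in the open state": the mean over *all* open
samples of conducting-polarity events. Events of polarity opposite to the
holding potential's conducting sign are excluded from conductance
estimates as artifacts; any conducting level counts as open for Po
(substate occupancy is not separated out).

## The simulator

Ground truth is a continuous-time Markov chain over conductance states,
drawn by Gillespie simulation and rendered through the acquisition chain:
Ohmic currents (`G * V / 1000`, pS x mV -> pA, positive current = cations
cis to trans), a constant offset when an ionic gradient is imposed, a
mains sinusoid, baseline drift, and white Gaussian noise, low-pass
filtered by a causal 4-pole Butterworth at 500 Hz and sampled at 10 kHz.
Choices worth stating:

* The white-noise SD is specified *post-filter* (what a user reads off a
  closed-channel trace) and rescaled before filtering via the filter's
  mean-square gain.
* Drift is a first-order Gauss–Markov (Ornstein–Uhlenbeck) process with a
  0.5 Hz corner, so its power sits below the 2 Hz exclusion — matching
  the rationale for excluding that band.
* The filter topology is a convention: amplifiers name only the corner.
  A causal (forward-only) filter is used deliberately; its settling tails
  and ~13% step overshoot are exactly the artifacts the estimators must
  tolerate.
* Ca2+ dependence enters kinetically: the closed-state exit rate is set to
  \(k_\mathrm{close}\, p/(1-p)\) with \(p\) the Hill-curve occupancy, so a
  two-state channel's stationary Po equals the Hill curve exactly.
* The default multi-substate scheme (closed ↔ 300 pS substate ↔ 1300 pS
  full open, plus a 600 pS flicker state of ~2 ms mean dwell) reproduces
  the qualitative fingerprint of megachannel records — several histogram
  peaks, a dominant subconductance, brief flickers — without inventing
  kinetics beyond that; rates are set for ~2/3 closed occupancy and 25 ms
  full-open dwells so stable top-level events are plentiful in 60 s.
* Gating rates are voltage-independent: the mild experimental preference
  for open states at depolarized voltages has no published functional
  form, so it is documented as out of model rather than guessed.

Half-activation and asymptotic Po of the Ca2+ activation are not
published quantities; the packaged titration scenario fixes them once at
`k_half = 0.6` mM (mid-titration on a 0.1–3 mM series) and
`po_max = 0.2` with `k_close = 50` s⁻¹ — values a bilayer
electrophysiologist would call realistic for a modest-Po megachannel —
and states them in the configuration. What the simulator does *not*
emulate: membrane-to-membrane heterogeneity between experiments, multiple
simultaneous insertions, voltage-dependent kinetics, and electrode/access
artifacts. Passing tests therefore demonstrate estimator correctness
under the modelled acquisition chain, not robustness to every pathology
of real bilayer data.

## Dose–response and group statistics

The Hill fit runs in log space for \(K\) and \(n\) (positivity without
constraints; the model is a logistic in log concentration) with
Levenberg–Marquardt, SEM weights when available, up to 20 jittered
restarts, and an honest `converged` flag — never a fabricated estimate.
`ca = 0` rows are excluded (the model forces zero there). The reported SE
of \(n\) comes from the fit covariance via the delta method, as a fitting
program would print it. Two caveats belong with that number: a ±1-SE
interval nominally covers the truth only ~68% of the time (less with few
residual degrees of freedom), and when SEM weights are themselves
estimated from 3–4 replicates the SE is a noisy quantity. Note also that
for a two-state channel the band-limited current variance scales as
\(p(1-p)\) plus a noise floor, not as \(p\): a Hill fit to PSA therefore
recovers a slightly smaller apparent \(n\) than the generating occupancy
coefficient (about −5% under the packaged titration), an intrinsic
property of variance-based activity statistics worth remembering when
comparing PSA- and Po-derived cooperativities.

The I–V fit is ordinary least squares; its intercept absorbs the constant
current offset imposed by an ionic gradient (auto mode), or a known
offset (e.g. the 13 pA shift of a Ca2+ gradient) can be subtracted first.
Group comparisons use the Mann–Whitney U with midranks; the p value is
exact by full enumeration when `n1 + n2 <= 12` without ties, otherwise a
tie-corrected, continuity-corrected normal approximation, and the output
says which. No multiplicity adjustment is applied, matching common
practice in this literature; the comparison table carries an explicit
`unadjusted` flag.

## Problem sizes and numerical conventions

The packaged scenarios use 60 s records at 10 kHz (600,000 samples); the
titration design is 23 recordings over six concentrations (0.1–3 mM,
replicates 4/4/4/4/4/3), mirroring a realistic experiment count, and
recovery statistics in the tests summarize 25 independent replications of
that design. Traces are written with a 0.1 fA amplitude quantum and
index-times-interval time stamps, so round-trips are lossless at the
noise floor. All derived seeds stay below 2^31; every simulation output
is bit-reproducible given its seed. Degenerate inputs are handled
explicitly: absorbing Markov states are permitted; a record with no
histogram peak near 0 pA raises a baseline-not-found error rather than
guessing; conductances are reported absent (NA), not zero, when no
qualifying event exists; and `v_cis = 0` is an error for conductance
estimators.

## Known limitations

Threshold idealization inflates Po slightly on heavily filtered, fast
gating records (filter tails above threshold at each transition); the
effect is proportional to the transition rate and largely cancels out of
Hill-coefficient estimates, but absolute Po values at high switching rates
carry a positive bias of a few percent. G_mean inherits a complementary
small negative bias from edge samples. No hidden-Markov idealization,
dwell-time fitting, or multi-channel decomposition is attempted — the
amplitude-threshold idealizer mirrors the few-insertion regime the
recordings come from.
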