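Package: bilayerPSA
Title: Single-Channel Current Analysis for Planar Lipid Bilayer Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for Ca2+-activated high-conductance channel
    recordings in planar lipid bilayers: power-spectrum-area (PSA) activity
    statistic with baseline-drift and line-noise exclusion bands, noise-band
    idealization with open probability and mean/maximal conductance under a
    10-ms stability rule, amplitude histograms with substate peaks, Hill
    dose-response and linear current-voltage fitting with constant-offset
    correction, and exact Mann-Whitney group comparison. Includes a synthetic
    recording generator (continuous-time Markov gating over multi-conductance
    states rendered through an Ohmic, filtered, noisy acquisition chain) and
    readers/writers for Axon Text Format and CSV traces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
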