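Package: windfa
Title: Windowed Detrended Fluctuation Analysis for Event-Locked Biosignals
Version: 1.0.0
Authors@R: person("windfa", "developers", role = c("aut", "cre"),
    email = "windfa@example.org")
Description: Detrended fluctuation analysis (DFA) with a floating-window
    extension for time-resolved scaling-exponent trajectories in
    multichannel biosignals such as EEG. Includes zero-phase Butterworth
    band-pass and notch preprocessing, event-aligned epoching, normalized
    response segments with their growth slope, nonparametric (Mann-Whitney)
    group comparison with per-channel difference maps, and a ground-truthed
    synthetic cohort generator based on fractional Gaussian noise with
    event-locked Hurst-exponent modulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
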