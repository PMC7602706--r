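# windfa — windowed detrended fluctuation analysis for event-locked biosignals

`windfa` quantifies long-range temporal correlations in multichannel
biosignals (EEG-type recordings) and, crucially, how they change around
events. Its target use case: motor-task EEG experiments where subjects
clench a hand on an audio cue and unclench on a second cue, and where the
question is how the scaling of the signal's fluctuations responds to the
movement — and whether that response differs between groups (e.g. young vs
elderly adults) or hands (dominant vs non-dominant).

## The method

Detrended fluctuation analysis (DFA) integrates a mean-centred signal into
a profile y(k) = Σ_{i≤k}(x_i − ⟨x⟩), detrends it piecewise over segments of
length *n*, and measures the RMS fluctuation F(n). Power-law behaviour
F(n) ∼ n^α defines the scaling exponent α: 0.5 for uncorrelated noise,
0.5–1 for persistent long-range correlations, >1 for integrated dynamics.
For fractional Gaussian noise with Hurst exponent H, α = H.

On top of classical DFA, the package provides:

- **Floating-window DFA** — α evaluated over a sliding window (default 2 s
  / 500 samples at 250 Hz, 0.1 s step) yielding a time-resolved trajectory
  α(t);
- **Preprocessing** — zero-phase order-4 Butterworth band-pass (1–100 Hz)
  and 50 Hz notch, event-aligned epoching (−2 s … +12 s around the cue);
- **Response metrics** — per-trial α(t) segments normalized to 1.0 at each
  movement onset (clench / unclench), their growth slope r = dα/dt with OLS
  standard errors, and two-stage (trials → subjects) averaging;
- **Group statistics** — exact / tie-corrected Mann–Whitney tests, a full
  channel × segment × hand-condition report, LH–RH contrasts, and a
  normalized per-channel group difference map;
- **A ground-truthed synthetic cohort generator** — fGn with event-locked
  Hurst modulation, calibrated by an exact second-moment model of the whole
  measurement chain so that requested group response slopes are what the
  pipeline actually measures; every drawn parameter lands in a manifest for
  recovery testing.

## Worked example

```r
library(windfa)

# 1. classical DFA recovers alpha = H on fractional Gaussian noise
x <- generate_fgn(0.75, 16384, seed = 7)
dfa(x)
#> DFA scaling fit: alpha = 0.7488 (lg n in [1.20, 3.61], 10 points, residual RMS 0.0166)

# 2. simulate a small two-group cohort and run the full pipeline
spec <- cohort_spec(n_subjects = 4, trials_per_hand = 6, trials_kept_per_hand = 6,
                    channels = c("C4", "C3"),
                    channel_gain = c(C4 = 1, C3 = 0.8), seed = 7)
co <- generate_cohort(spec)     # calibrates bumps, synthesizes recordings + events
an <- analyze_cohort(co)        # filter -> epoch -> sliding alpha -> slopes -> stats
an
#> windfa_analysis of 8 subjects, 2 channel(s)
#> significant cells (p < 0.05 ):
#>  channel  segment hand_condition    p_value
#>       C4 unclench            all 0.02857143
#>       C4 unclench             RH 0.02857143
#>       C3   clench            all 0.02857143
#>       C3 unclench             RH 0.02857143

subset(an$report, segment == "clench" & hand_condition == "all")
#>   channel segment hand_condition mean_elderly se_elderly n_elderly mean_young
#> 1      C4  clench            all        0.166     0.0341         4     0.0789
#> 7      C3  clench            all        0.128     0.0268         4     0.0715
#>   se_young n_young  U p_value significant
#> 1  0.02005       4 14  0.1143       FALSE
#> 7  0.00578       4 16  0.0286        TRUE

an$channel_map
#>   channel   raw normalized
#> 1      C4 0.087       1.00
#> 2      C3 0.056       0.64
```

The report rows give each group's mean response slope r (per second of
normalized α growth) with its standard error across subjects, the
Mann–Whitney U and two-sided p; the elderly group was generated with the
larger clench response, and the channel map correctly localizes the
strongest group difference at full-gain C4 (C3 was generated at 0.8 gain).
At this toy size (4 subjects per group, 6 trials per hand) only some cells
reach significance — the acceptance suite runs the full-size recovery.

A command-line front end covering the same stages ships in
`inst/exec/windfa`:

```sh
windfa dfa --input recording.csv --order 1 --fit-range 1.2:2.5
windfa sliding --input recording.csv --window 500 --step 25
windfa simulate --subjects 10 --trials 30 --kept 15 --seed 42 --out cohort/
windfa analyze --input cohort/ --out results/
```

## Package layout

- `R/dfa-core.R`, `src/windfa.cpp` — DFA primitives (compiled inner loops);
- `R/sliding-dfa.R` — floating-window trajectories and smoothness checks;
- `R/preprocess.R` — filters, recordings, events, epochs;
- `R/response-metrics.R` — normalized segments, slopes, averaging;
- `R/group-stats.R` — Mann–Whitney, reports, channel maps;
- `R/synthetic-fgn.R`, `R/synthetic-cohort.R` — generators and their
  calibration model;
- `R/io.R`, `R/pipeline.R`, `R/cli.R` — file formats, orchestration, CLI.

The methods vignette (`vignettes/windowed-dfa.Rmd`) documents the model,
every tunable parameter, the generator's stated world, the calibration
mathematics, and known limitations.
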