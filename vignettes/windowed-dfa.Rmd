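---
title: "Windowed DFA for event-locked biosignals: models, parameters, and design choices"
author: "windfa developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed DFA for event-locked biosignals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(windfa)
```

## The problem

Electrical activity of the cortex, like many physiological signals, carries
long-range temporal correlations: its fluctuations are statistically
self-similar over a wide range of time scales, and the degree of persistence
is summarized by a single scaling exponent. When a subject performs a motor
task -- clenching a hand into a fist on an audio cue, holding it, and
releasing on a second cue -- the correlation structure of sensorimotor EEG
transiently changes. `windfa` provides the machinery to quantify those
transient changes: classical detrended fluctuation analysis (DFA), a
floating-window extension that resolves the scaling exponent in time, the
event-locked response statistics built on top of it, nonparametric group
comparison, and a fully ground-truthed synthetic cohort generator for
validating the entire chain.

## DFA and the scaling exponent

For a signal $x(i)$, $i = 1, \dots, N$, DFA proceeds by

1. integrating the mean-centred signal into a profile
   $y(k) = \sum_{i \le k} (x(i) - \langle x \rangle)$;
2. cutting the profile into $\lfloor N/n \rfloor$ non-overlapping segments of
   length $n$, starting from the first sample;
3. removing a least-squares polynomial trend (order 1 by default) from each
   segment;
4. computing the RMS residual $F(n)$ over the covered samples;
5. repeating over a grid of scales $n$; and
6. fitting $\lg F$ vs $\lg n$ by least squares: the slope is the scaling
   exponent $\alpha$ in $F(n) \sim n^\alpha$.

White noise gives $\alpha = 1/2$; persistent power-law correlations give
$1/2 < \alpha < 1$; anti-persistent signals give $\alpha < 1/2$; integrated
(random-walk-like) signals give $\alpha > 1$. For fractional Gaussian noise
(fGn) with Hurst exponent $H$, DFA yields $\alpha = H$, which the test suite
uses as an analytic oracle.

```{r dfa-example}
set.seed(1)
dfa(cumsum(rnorm(8192)))$alpha   # integrated white noise: about 1.5
```

Numerical choices worth knowing:

* **Remainder samples.** When $n \nmid N$, segments are taken from the start
  and the tail is discarded; $F(n)$ is normalized by the covered sample
  count, not $N$. (A both-ends variant exists in the literature; the
  simpler single-pass reading is used here and is what the oracle tests
  pin down.)
* **Scale grid.** Log-spaced, 12 points by default, from $n_{\min} = 8$
  (safely above `detrend_order + 2`) to $n_{\max} = \lfloor N/4 \rfloor$ so
  the largest scale still averages four segments.
* **Fit range.** For full-length recordings the default fit uses
  $\lg n \in [1.2, \lg n_{\max}]$, the conventional long-range-correlation
  window; short windowed excerpts fit over their whole grid. Logarithms are
  base 10 throughout.
* **Degenerate input.** A constant signal has $F(n) \equiv 0$; `dfa()`
  returns `NaN` with a warning rather than inventing a number. Individual
  zero-$F$ scales are dropped from fits with a warning; fewer than three
  usable scales is an error.

## The floating window

`sliding_alpha()` applies the whole DFA chain to successive windowed
excerpts. The defaults follow the motor-task protocol this package targets:
a 500-sample window (2 s at 250 Hz) stepped by 25 samples (0.1 s), each
window analysed in complete isolation over scales $n \in [8, 125]$
($\lg n \lesssim 2.1$; a window must hold at least 100 samples for the
fit to be meaningful, hence the warning below that length). The exponent is
attributed to the window *centre* by default: the protocol's figures do not
disambiguate the anchor, and centre anchoring avoids systematic latency
distortion; `anchor` is configurable and changes nothing but the time axis.

The floating window is a low-pass filter of $\alpha(t)$: larger windows give
smoother trajectories with smaller maximum jumps (exposed by
`trajectory_smoothness()` and asserted in the acceptance suite over
$W \in \{250, 500, 1000, 1500\}$), at the price of temporal resolution. A
500-sample window is the documented trade-off.

## Preprocessing and epoching

`bandpass_filter()` implements the 1--100 Hz Butterworth band-pass as a
cascade of order-4 high-pass and low-pass stages designed by bilinear
transform, each applied forward-backward (zero phase, so response latencies
are not biased); `notch_filter()` is a Q = 30 biquad at 50 Hz, also
zero-phase. The filter order, phase convention and notch width are not
dictated by the protocol and are configuration choices. Epochs run from 2 s
before to 12 s after the first audio cue by default, spanning baseline,
the 4--5 s active phase, the unclench response and the following pause;
indexing is 0-based with half-open sample intervals, and out-of-bounds
events are skipped with a warning. Manual artifact rejection is modelled
only as a `keep` mask in the event table.

## Response metrics

For each trial, channel and movement segment (clench at the first cue,
unclench at the second) the trajectory is *normalized to the value at the
grid point nearest the segment onset*, so every response starts at exactly
1.0, and its growth rate $r = d\alpha/dt$ is the OLS slope over the first
2 s of the segment (the fit interval is configurable; the protocol's
figures do not print theirs). Normalization happens per trial, before any
averaging. Averaging is two-stage -- trials within subject, then subjects
within group, with the group SE taken across subjects -- so subjects are
weighted equally regardless of trial counts. Slopes are reported both from
the group-averaged curve and as the per-subject values the nonparametric
tests need; with the per-trial normalization convention the two are close
but not identical, and both are exposed.

The second cue time is needed to place the unclench segment, so event
tables carry an optional `unclench_s` column; when absent it defaults to
`onset_s + 4.5` (the middle of the 4--5 s active-phase range).

## Group statistics

`mann_whitney()` uses the exact U distribution (computed by the standard
partition-count recurrence) for $n_1 + n_2 \le 20$ without ties and a
tie-corrected normal approximation with continuity correction otherwise;
tests are two-sided. `channel_difference_map()` reports the signed
per-channel difference of group slopes and a normalized version (division
by the maximum absolute difference, so the strongest channel is $\pm 1$ --
an interpretation, with z-scoring available as an alternative). No
multiple-testing correction is applied by default, matching per-channel
reporting conventions; Benjamini-Hochberg is available as an option.

## The synthetic cohort generator

Real recordings for this protocol are not bundled, so validation rests on a
generator that carries exactly the statistical structure the analysis
measures, with every parameter recorded in a manifest.

**Signal model.** Each channel is unit-variance fGn whose Hurst exponent is
modulated by the events: a clench bump from the first cue to shortly before
the second, and an unclench bump from the second cue held for 2.5 s, each
realized by equal-power raised-cosine crossfades (0.5 s, well below the 2 s
analysis window, so transitions are analysis-limited) between independent
fGn processes. White measurement noise is added at 10 dB SNR and the result
scaled to 10 uV RMS. Baseline $H$ is 0.55. Because fGn confines
$\alpha < 1$, the default response-slope targets (relative
response gains of 14--23%) need substantial headroom above baseline: with a
baseline near 0.9 every clench target would clip at $H \to 1$ and the
group contrast would collapse, so the lower baseline is a deliberate
feasibility choice -- the cost is that absolute $\alpha$ levels sit below
the $\approx 1$ typical of real EEG, which the response statistics (built
on normalized $\alpha$) do not depend on.

**Calibration.** The generator's contract is a target *measured* slope $r$
per group, hand and segment (defaults are the C4 column of the reference
slope table). Because the floating window smooths the bump, the onset
normalization lands mid-transition, and the band-pass filter and noise
floor attenuate the response, the Hurst increment needed for a given
measured $r$ is found by root-finding against an exact second-moment model
of the whole measurement chain: the expected squared fluctuation function
of each analysis window follows from the window's covariance (mixture
weights times fGn Toeplitz blocks, spectrally filtered by the squared
magnitude of the zero-phase filter chain, centred and prefix-summed into
the profile covariance), and the window's model $\alpha$ is the log-log
OLS slope of $E[\log F^2]$, including the second-order Jensen correction
$E[\log F^2] = \log E[F^2] - \mathrm{Var}[F^2]/(2\,E[F^2]^2)$ that the
log-domain estimator incurs. (The model evaluates its expected trajectory
on a 0.2 s grid; the expectation curve is smooth, and the OLS slope
matches the 0.1 s estimator grid to better than 1%.) The same model, tabulated over subject
baseline and increment and interpolated, provides each subject's
ground-truth $r$ in the manifest, so clipping and inter-subject
variability are reflected exactly rather than linearized.

**Variability and clipping.** Subject baselines are drawn with SD 0.05 and
bump amplitudes with 20% relative SD; increments that would push $H$ past
0.98 are clipped, flagged in the manifest, and folded into that subject's
truth value. Channel topography multiplies increments by a gain map
(1.0 at C4/Cz, 0.8 at C3/FC4/CP4, 0.5 elsewhere), an interpretation of the
sensorimotor focus of the reference study's channel map.

**What a green test does and does not establish.** The generator emulates
the *correlation dynamics* the analysis measures -- nothing else. It has no
oscillatory EEG rhythms, no volume conduction or inter-channel correlation,
no artifacts, and trial chunks are independent realizations joined at
trial boundaries (seams fall 10+ s after each onset, outside all fit
intervals). Recovery tests therefore validate the analysis chain and its
statistics, not the physiological realism of the input.

**Known estimator bias.** Per-trial normalization divides by a noisy
$\alpha(0)$; the induced ratio bias inflates measured slopes by roughly
+0.01/s independent of group and bump size. It cancels in group contrasts
and stays well inside the recovery tolerances for group means; it is left
uncorrected and documented here.

## Scaling of the validation experiments

The end-to-end acceptance experiments run on reduced cohorts to stay inside
a desk-scale time budget: slope recovery uses 20 seeds of 10+10 subjects
with 8 kept trials per hand at the C4 target channel (group sizes are kept
at the protocol's 10 per group because the ordering check is powered by
subjects); the topographic check pits C4/Cz against 0.5-gain channels,
since the 0.8-gain neighbours are within the trial-noise floor at this
size; the null-cohort check uses 12 seeds of 5+5 subjects. Monte-Carlo
characterization with common random numbers (1200 paired trials) puts the
recovered group means within 2--5% of truth and the group contrast at
0.96 +/- 0.01 of its generated value for the full-size configuration.

## Limitations

* Pure fGn baselines place absolute $\alpha$ near 0.55 rather than the
  $\approx 1$ of resting EEG; all response statistics are normalized and
  unaffected, but absolute trajectory levels are not comparable to real
  recordings.
* ICA-based artifact removal, re-referencing and scalp-map rendering are
  out of scope; the per-channel difference map is numeric only.
* The EDF reader/writer is a minimal 16-bit continuous-recording
  implementation for interchange of synthetic data, not a general EDF+
  library.
* The exact Mann-Whitney path requires untied data; midrank/tie-corrected
  approximation is used otherwise (with a note).
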