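fs <- 250
tt <- (0:(20 * fs - 1)) / fs
# steady-state amplitude of a sinusoid, measured on the interior
sine_amp <- function(x) {
  n <- length(x)
  sqrt(2 * mean(x[round(n * 0.25):round(n * 0.75)]^2))
}

test_that("band-pass gain: DC rejected, passband flat, stopband attenuated", {
  dc <- bandpass_filter(rep(10, length(tt)), 1, 100, 4, sampling_rate = fs)
  expect_lt(max(abs(dc[1000:4000])), 10 * 10^(-20 / 20)) # > 20 dB down
  s10 <- bandpass_filter(sin(2 * pi * 10 * tt), 1, 100, 4, sampling_rate = fs)
  expect_lt(abs(sine_amp(s10) - 1), 0.05)
  s120 <- bandpass_filter(sin(2 * pi * 120 * tt), 1, 100, 4, sampling_rate = fs)
  expect_lt(sine_amp(s120), 10^(-20 / 20))
  expect_error(bandpass_filter(tt, 0, 100, sampling_rate = fs), "Nyquist")
  expect_error(bandpass_filter(tt, 1, 130, sampling_rate = fs), "Nyquist")
})

test_that("notch removes 50 Hz, spares neighbours and passband", {
  n50 <- notch_filter(sin(2 * pi * 50 * tt), 50, 30, sampling_rate = fs)
  expect_lt(sine_amp(n50), 0.1)
  n45 <- notch_filter(sin(2 * pi * 45 * tt), 50, 30, sampling_rate = fs)
  n55 <- notch_filter(sin(2 * pi * 55 * tt), 50, 30, sampling_rate = fs)
  expect_gt(sine_amp(n45), 10^(-3 / 20))  # < 3 dB
  expect_gt(sine_amp(n55), 10^(-3 / 20))
  n10 <- notch_filter(sin(2 * pi * 10 * tt), 50, 30, sampling_rate = fs)
  expect_lt(abs(sine_amp(n10) - 1), 0.02)
  expect_equal(notch_filter(numeric(1000), 50, sampling_rate = fs),
               numeric(1000))
})

test_that("filtering is linear", {
  set.seed(1)
  x <- rnorm(3000); y <- rnorm(3000)
  f <- function(v) bandpass_filter(v, 1, 100, 4, sampling_rate = fs)
  lhs <- f(2 * x + 3 * y)
  rhs <- 2 * f(x) + 3 * f(y)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-8)
})

test_that("epoch extraction does exact index arithmetic and preserves content", {
  set.seed(2)
  X <- matrix(rnorm(10000 * 2), ncol = 2)
  rec <- eeg_recording(X, fs, c("C3", "C4"))
  ev <- event_table(onset_s = 20, hand = "RH", cue_duration_s = 0.75)
  eps <- extract_epochs(rec, ev, pre_s = 2, post_s = 12)
  expect_length(eps, 1)
  expect_equal(nrow(eps[[1]]$samples), 3500)
  expect_identical(eps[[1]]$samples, X[4501:8000, ],
                   ignore_attr = TRUE) # samples [4500, 8000), 0-based
  expect_equal(eps[[1]]$t0_offset_s, 2)
})

test_that("out-of-bounds events are skipped with a warning; labels kept in order", {
  set.seed(3)
  rec <- eeg_recording(matrix(rnorm(250 * 500), ncol = 1), fs, "Cz")
  hands <- rep(c("LH", "RH"), length.out = 30)
  ev <- event_table(onset_s = seq(10, 480, length.out = 30), hand = hands,
                    cue_duration_s = 0.3)
  eps <- extract_epochs(rec, ev, 2, 12)
  expect_length(eps, 30)
  expect_equal(vapply(eps, `[[`, "", "hand"), hands)
  ev_bad <- event_table(onset_s = c(1, 50), hand = c("LH", "RH"),
                        cue_duration_s = 0.3)
  expect_warning(eps2 <- extract_epochs(rec, ev_bad, 2, 12), "out of bounds")
  expect_length(eps2, 1)
  # keep mask drops trials
  ev$keep[seq(1, 30, 2)] <- FALSE
  expect_length(extract_epochs(rec, ev, 2, 12), 15)
})

test_that("filter-then-epoch agrees with epoch-then-filter away from edges", {
  set.seed(4)
  rec <- eeg_recording(matrix(rnorm(250 * 60), ncol = 1), fs, "C4")
  ev <- event_table(onset_s = 25, hand = "LH", cue_duration_s = 0.3)
  a <- extract_epochs(bandpass_filter(rec, 1, 100, 4), ev, 2, 12)[[1]]$samples
  b <- bandpass_filter(extract_epochs(rec, ev, 2, 12)[[1]]$samples,
                       1, 100, 4, sampling_rate = fs)
  interior <- (2 * fs + 1):(nrow(a) - 2 * fs) # 2 s edge margin (1 Hz stage)
  expect_lt(max(abs(a[interior, 1] - b[interior, 1])) / sd(a[, 1]), 0.02)
})

test_that("event_table validates its invariants", {
  expect_error(event_table(c(2, 1), c("LH", "RH"), 0.3), "increasing")
  expect_error(event_table(c(1, 2), c("XX", "RH"), 0.3), "LH")
  expect_error(event_table(1, "LH", 0.3, unclench_s = 0.5), "unclench")
  expect_error(eeg_recording(matrix(0, 5, 2), 250, c("a", "a")), "unique")
})
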