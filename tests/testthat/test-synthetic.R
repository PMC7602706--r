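test_that("fGn generator is deterministic and has the right second moments", {
  x1 <- generate_fgn(0.75, 4096, seed = 7)
  x2 <- generate_fgn(0.75, 4096, seed = 7)
  expect_identical(x1, x2)
  # H = 0.5 is white: lag-1 autocorrelation within 3 / sqrt(N)
  w <- generate_fgn(0.5, 65536, seed = 1)
  r1 <- cor(w[-1], w[-length(w)])
  expect_lt(abs(r1), 3 / sqrt(65536))
  # sample autocovariance at lags 1..10 vs the closed form (H = 0.75)
  lags <- 1:10
  emp <- sapply(1:6, function(s) {
    x <- generate_fgn(0.75, 65536, seed = 10 + s)
    vapply(lags, function(k) mean(x[-(1:k)] * x[seq_len(65536 - k)]),
           numeric(1))
  })
  theor <- fgn_autocov(0.75, lags)
  mc_se <- apply(emp, 1, sd) / sqrt(ncol(emp))
  expect_true(all(abs(rowMeans(emp) - theor) < 3 * mc_se + 5e-4))
  # unit variance (seed-averaged: the sample variance of strongly persistent
  # fGn has a heavy MC error in any single realization)
  v <- mean(vapply(1:4, function(s) var(generate_fgn(0.7, 65536, seed = s)),
                   numeric(1)))
  expect_lt(abs(v - 1), 0.05)
})

test_that("DFA recovers alpha = H on fGn", {
  for (H in c(0.3, 0.6, 0.9)) {
    a <- mean(vapply(1:10, function(s)
      dfa(generate_fgn(H, 65536, seed = 50 + s))$alpha, numeric(1)))
    expect_lt(abs(a - H), 0.05)
  }
})

test_that("hurst_profile validates geometry and crossfades", {
  expect_error(hurst_profile(c(0, 5), c(4, 10), c(0.5, 0.8)), "contiguous")
  expect_error(hurst_profile(0, 10, 1.2), "H must lie")
  expect_error(hurst_profile(c(0, 2), c(2, 4), c(0.5, 0.8), crossfade_s = 3),
               "crossfade longer")
  pr <- hurst_profile(c(0, 4), c(4, 8), c(0.5, 0.9), crossfade_s = 1)
  h <- hurst_timecourse(pr, c(1, 4, 7))
  expect_equal(h, c(0.5, 0.7, 0.9))
})

test_that("flat-profile modulated signal is distributionally fGn", {
  pr <- hurst_profile(c(0, 6, 12), c(6, 12, 18), rep(0.5, 3), crossfade_s = 0.5)
  a_mod <- unlist(lapply(1:8, function(s)
    sliding_alpha(generate_modulated_signal(pr, 250, seed = s), 250,
                  step = 250)$alphas))
  a_fgn <- unlist(lapply(1:8, function(s)
    sliding_alpha(generate_fgn(0.5, 4500, seed = 300 + s), 250,
                  step = 250)$alphas))
  ks <- suppressWarnings(ks.test(a_mod, a_fgn))
  expect_gt(ks$p.value, 0.01)
})

test_that("a Hurst bump appears, peaks inside the bump, and two bumps give two humps", {
  pr <- hurst_profile(c(0, 8, 11), c(8, 11, 20), c(0.5, 0.9, 0.5),
                      crossfade_s = 0.5)
  tt <- NULL
  am <- rowMeans(vapply(1:8, function(s) {
    tr <- sliding_alpha(generate_modulated_signal(pr, 250, seed = s), 250)
    tt <<- tr$times
    tr$alphas
  }, numeric(181)))
  t_peak <- tt[which.max(am)]
  expect_gt(t_peak, 8)
  expect_lt(t_peak, 11)
  # two bumps -> two local maxima of the trial-averaged trajectory
  pr2 <- hurst_profile(c(0, 6, 9, 14, 17), c(6, 9, 14, 17, 24),
                       c(0.5, 0.85, 0.5, 0.85, 0.5), crossfade_s = 0.5)
  am2 <- rowMeans(vapply(1:8, function(s) {
    sliding_alpha(generate_modulated_signal(pr2, 250, seed = 30 + s), 250)$alphas
  }, numeric(221)))
  tt2 <- sliding_alpha(generate_modulated_signal(pr2, 250, seed = 1), 250)$times
  in1 <- am2[tt2 > 6 & tt2 < 9]; in2 <- am2[tt2 > 14 & tt2 < 17]
  dip <- am2[tt2 > 10.5 & tt2 < 12.5]
  expect_gt(max(in1), max(dip) + 0.05)
  expect_gt(max(in2), max(dip) + 0.05)
})

test_that("modulated-signal crossfade preserves variance", {
  pr <- hurst_profile(c(0, 5), c(5, 10), c(0.4, 0.8), crossfade_s = 1)
  v <- vapply(1:6, function(s)
    var(generate_modulated_signal(pr, 250, seed = s)), numeric(1))
  expect_lt(abs(mean(v) - 1), 0.1)
})

test_that("cohort generation is reproducible with the documented cardinalities", {
  spec <- cohort_spec(n_subjects = 1, trials_per_hand = 30,
                      trials_kept_per_hand = 15, channels = "C4",
                      channel_gain = c(C4 = 1), seed = 11)
  co <- generate_cohort(spec)
  expect_length(co$subjects, 2) # one per group
  ev <- co$subjects[[1]]$events
  expect_equal(nrow(ev), 60)
  expect_equal(sum(ev$hand == "LH"), 30)
  expect_equal(sum(ev$keep[ev$hand == "LH"]), 15)
  expect_equal(sum(ev$keep[ev$hand == "RH"]), 15)
  expect_equal(unname(ev$cue_duration_s[ev$hand == "LH"][1]), 0.3)
  expect_equal(unname(ev$cue_duration_s[ev$hand == "RH"][1]), 0.75)
  expect_true(all(diff(ev$onset_s) > 0))
  co2 <- generate_cohort(spec)
  expect_identical(co$subjects[[2]]$recording$samples,
                   co2$subjects[[2]]$recording$samples)
  # channel variance close to its specified value
  v <- var(co$subjects[[1]]$recording$samples[, 1])
  v_spec <- spec$amplitude_uV^2 * (1 + 10^(-spec$noise_snr_db / 10))
  expect_lt(abs(v / v_spec - 1), 0.05)
  # default spec carries the documented experiment shape
  d <- cohort_spec()
  expect_equal(d$n_subjects, 10)
  expect_equal(d$trials_per_hand, 30)
  expect_equal(d$trials_kept_per_hand, 15)
  expect_length(d$channels, 31)
  expect_equal(d$sampling_rate, 250)
  expect_equal(unname(d$channel_gain[c("C4", "Cz", "C3", "Pz")]),
               c(1, 1, 0.8, 0.5))
})

test_that("recovered slope grows monotonically with the generated amplitude", {
  # amplitude ladder encoded as channel gains (the generator scales the
  # Hurst increment linearly with gain); single-group mini-cohorts
  gains <- c(g00 = 1e-6, g25 = 0.25, g50 = 0.5, g75 = 0.75, g100 = 1)
  r_by_gain <- rowMeans(vapply(1:4, function(s) {
    spec <- cohort_spec(n_subjects = 1, trials_per_hand = 6,
                        trials_kept_per_hand = 6, channels = names(gains),
                        channel_gain = gains, seed = 400 + s,
                        baseline_sd = 0, amplitude_rel_sd = 0)
    co <- suppressWarnings(generate_cohort(spec))
    an <- analyze_cohort(co)
    sl <- an$slopes
    sl <- sl[sl$group == "elderly" & sl$segment == "clench" &
             sl$hand_condition == "all", ]
    sl$r[match(names(gains), sl$channel)]
  }, numeric(5)))
  expect_equal(cor(r_by_gain, gains, method = "spearman"), 1)
})
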