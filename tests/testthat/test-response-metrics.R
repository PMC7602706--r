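mk_traj <- function(times, alphas) {
  structure(list(times = times, alphas = alphas, window_len = 500L,
                 step = 25L, anchor = "center", sampling_rate = 250,
                 dfa_params = list()),
            class = "alpha_trajectory")
}

test_that("normalize_segment divides by the value at the nearest grid point", {
  tr <- mk_traj(seq(0, 0.2, 0.1), c(0.9, 0.99, 1.08))
  r <- normalize_segment(tr, 0, 0.2)
  expect_equal(r$values, c(1.0, 1.1, 1.2))
  expect_identical(r$values[1], 1)
  tr2 <- mk_traj(c(0, 0.1), c(1.3, 1.3))
  expect_equal(normalize_segment(tr2, 0, 0.1)$values, c(1, 1))
  # elementwise oracle on an arbitrary segment
  set.seed(1)
  tr3 <- mk_traj(seq(-1, 5, 0.1), runif(61, 0.5, 1.5))
  r3 <- normalize_segment(tr3, 1.02, 3)   # snaps to the 1.0 grid point
  i0 <- which.min(abs(tr3$times - 1.02))
  ref <- tr3$alphas[tr3$times >= tr3$times[i0] - 1e-9 &
                    tr3$times <= 3 + 1e-9] / tr3$alphas[i0]
  expect_equal(r3$values, ref)
  # idempotence
  r4 <- normalize_segment(mk_traj(r3$times, r3$values), 0, max(r3$times))
  expect_equal(r4$values, r3$values)
  expect_error(normalize_segment(mk_traj(c(0, 1), c(-1, 1)), 0, 1),
               "non-positive")
  expect_error(normalize_segment(tr, -5, 0.2), "outside")
})

test_that("estimate_slope is exact on lines and matches the OLS oracle", {
  t <- seq(0, 2, 0.1)
  s <- estimate_slope(list(times = t, values = 1 + 0.1 * t))
  expect_equal(s$r, 0.1, tolerance = 1e-12)
  expect_equal(s$stderr, 0, tolerance = 1e-12)
  expect_equal(estimate_slope(list(times = t, values = rep(1, 21)))$r, 0)
  set.seed(2)
  v <- 1 + 0.07 * t + rnorm(21, 0, 0.01)
  s2 <- estimate_slope(list(times = t, values = v))
  expect_equal(s2$r, unname(naive_ols(t, v)["slope"]), tolerance = 1e-12)
  expect_error(estimate_slope(list(times = c(0, 1), values = c(1, 2))),
               "at least 3")
})

test_that("slope is equivariant under time rescaling and offset-after-normalization", {
  t <- seq(0, 2, 0.1)
  set.seed(3)
  v <- 1 + 0.1 * t + rnorm(21, 0, 0.02)
  r1 <- estimate_slope(list(times = t, values = v))$r
  r2 <- estimate_slope(list(times = 10 * t, values = v),
                       fit_interval_s = c(0, 20))$r
  expect_equal(r2, r1 / 10, tolerance = 1e-12)
  r3 <- estimate_slope(list(times = t, values = v + 5))$r
  expect_equal(r3, r1, tolerance = 1e-12)
})

test_that("trial and subject averaging obey the pointwise-mean and SE oracles", {
  t <- seq(0, 1, 0.5)
  mk <- function(v) list(times = t, values = v)
  # single trial is itself
  expect_equal(average_trials(list(mk(c(1, 1.1, 1.2))))$mean, c(1, 1.1, 1.2))
  # mirror-image trials cancel
  d <- c(0, 0.05, 0.1)
  av <- average_trials(list(mk(1 + d), mk(1 - d)))
  expect_equal(av$mean, rep(1, 3))
  # pointwise-mean oracle
  set.seed(4)
  vs <- replicate(5, runif(3), simplify = FALSE)
  av2 <- average_trials(lapply(vs, mk))
  expect_equal(av2$mean, Reduce(`+`, vs) / 5)
  expect_equal(av2$se, apply(do.call(cbind, vs), 1, sd) / sqrt(5))
  # subject level: hand-checked SE
  cu <- function(v) list(times = 0, mean = v, se = 0, n = 10, level = "subject")
  g <- average_subjects(list(cu(0.08), cu(0.12)))
  expect_equal(g$mean, 0.10)
  expect_equal(g$se, 0.02)
  expect_warning(average_subjects(list(cu(0.08))), "undefined")
  g1 <- suppressWarnings(average_subjects(list(cu(0.08))))
  expect_true(is.na(g1$se))
  # identical subjects -> SE 0
  expect_equal(average_subjects(list(cu(0.1), cu(0.1)))$se, 0)
  expect_error(average_trials(list(mk(1:3), list(times = c(0, 1), values = 1:2))),
               "common time grid")
})

test_that("two-stage averaging equals pooled averaging only for equal counts", {
  t <- 0
  mk <- function(v) list(times = t, values = v)
  # equal counts: 2 subjects x 2 trials
  s1 <- average_trials(list(mk(1.0), mk(1.2)))
  s2 <- average_trials(list(mk(1.4), mk(1.6)))
  two_stage <- average_subjects(list(s1, s2))$mean
  pooled <- mean(c(1.0, 1.2, 1.4, 1.6))
  expect_equal(two_stage, pooled)
  # unequal counts: two-stage weights subjects equally
  s1b <- average_trials(list(mk(1.0)))
  s2b <- average_trials(list(mk(1.4), mk(1.6), mk(1.8)))
  expect_equal(average_subjects(list(s1b, s2b))$mean, mean(c(1.0, 1.6)))
  expect_false(isTRUE(all.equal(average_subjects(list(s1b, s2b))$mean,
                                mean(c(1.0, 1.4, 1.6, 1.8)))))
})

test_that("lh_rh_contrast handles identical hands, channel averaging and exclusions", {
  sl <- data.frame(subject = rep("s1", 4),
                   channel = rep(c("C3", "C4"), each = 2),
                   hand = rep(c("LH", "RH"), 2),
                   r = c(0.11, 0.10, 0.13, 0.10))
  co <- lh_rh_contrast(sl)
  expect_equal(co$per_subject$abs, mean(c(0.01, 0.03)))
  # identical hands -> zero
  sl0 <- transform(sl, r = 0.1)
  expect_equal(lh_rh_contrast(sl0)$mean_abs, 0)
  # missing hand excluded with warning
  sl_miss <- rbind(sl, data.frame(subject = "s2", channel = "C3",
                                  hand = "LH", r = 0.2))
  expect_warning(co2 <- lh_rh_contrast(sl_miss), "missing a hand")
  expect_equal(co2$n_subjects, 1)
})
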