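test_that("build_profile matches hand computations and the cumulative-sum oracle", {
  expect_equal(build_profile(c(1, 2, 3)), c(-1, -1, 0))
  expect_equal(build_profile(rep(5, 10)), rep(0, 10))
  set.seed(64)
  x <- rnorm(64)
  expect_equal(build_profile(x), naive_profile(x), tolerance = 1e-12)
  expect_lt(abs(build_profile(x)[64]), 1e-9 * 64 * sd(x))
  expect_error(build_profile(c(1, NA, 3)), "non-finite")
  expect_error(build_profile(1), "at least 2")
})

test_that("fluctuation_function matches the naive loop oracle and rejects bad scales", {
  set.seed(7)
  x <- rnorm(64)
  prof <- build_profile(x)
  for (ord in 0:2) {
    fc <- fluctuation_function(prof, c(8L, 16L), detrend_order = ord)
    expect_equal(fc$fluctuations, naive_fluct(prof, c(8, 16), ord),
                 tolerance = 1e-10)
  }
  # zero profile (constant signal) -> F identically 0
  fc0 <- fluctuation_function(rep(0, 100), c(8L, 16L, 25L))
  expect_equal(fc0$fluctuations, c(0, 0, 0))
  expect_error(fluctuation_function(prof, c(16L, 8L)), "increasing")
  expect_error(fluctuation_function(prof, 40L), "floor")
  expect_error(fluctuation_function(prof, 2L, detrend_order = 1), "detrend_order")
})

test_that("oracle equivalence holds on random property cases (length <= 128)", {
  set.seed(99)
  for (i in 1:40) {
    N <- sample(16:128, 1)
    ord <- sample(0:2, 1)
    x <- rnorm(N) * 10^runif(1, -2, 2)
    prof <- build_profile(x)
    n_max <- N %/% 2
    sc <- sort(unique(sample((ord + 2):n_max, min(4, n_max - ord - 1))))
    fc <- fluctuation_function(prof, as.integer(sc), ord)
    ref <- naive_fluct(prof, sc, ord)
    expect_equal(fc$fluctuations, ref, tolerance = 1e-10)
  }
})

test_that("fit_scaling_exponent recovers exact and perturbed power laws", {
  mk <- function(scales, F) structure(
    list(scales = as.integer(scales), fluctuations = F, detrend_order = 1L),
    class = "fluctuation_curve")
  f1 <- fit_scaling_exponent(mk(c(8, 16, 32, 64), c(8, 16, 32, 64)))
  expect_equal(f1$alpha, 1, tolerance = 1e-12)
  expect_lt(f1$residual_rms, 1e-12)
  f2 <- fit_scaling_exponent(mk(c(8, 16, 32, 64), 3 * c(8, 16, 32, 64)^0.5))
  expect_equal(f2$alpha, 0.5, tolerance = 1e-12)
  # perturbed curve vs the closed-form OLS oracle
  set.seed(3)
  sc <- c(8, 16, 32, 64, 128)
  eps <- runif(5, -0.02, 0.02)
  Fv <- sc^0.7 * (1 + eps)
  f3 <- fit_scaling_exponent(mk(sc, Fv))
  ora <- naive_ols(log10(sc), log10(Fv))
  expect_equal(f3$alpha, unname(ora["slope"]), tolerance = 1e-12)
  expect_lt(abs(f3$alpha - 0.7), 0.02)
  # zero points excluded with warning; too few points rejected
  expect_warning(f4 <- fit_scaling_exponent(mk(sc, c(0, Fv[-1]))), "F\\(n\\) = 0")
  expect_equal(f4$n_points, 4L)
  expect_error(
    suppressWarnings(fit_scaling_exponent(mk(c(8, 16, 32), c(0, 0, 1)))),
    "fewer than 3")
})

test_that("degenerate constant signal yields NaN alpha, not an arbitrary value", {
  expect_warning(f <- dfa(rep(2.5, 400)), "alpha undefined")
  expect_true(is.nan(f$alpha))
})

test_that("alpha is invariant under scaling, offset and sign flip; F is equivariant", {
  set.seed(11)
  x <- rnorm(1024)
  prof <- build_profile(x)
  sc <- dfa_scales(1024)
  F1 <- fluctuation_function(prof, sc)$fluctuations
  F2 <- fluctuation_function(build_profile(-3.7 * x), sc)$fluctuations
  expect_equal(F2, 3.7 * F1, tolerance = 1e-10)
  expect_equal(fluctuation_function(build_profile(-x), sc)$fluctuations, F1,
               tolerance = 1e-12)
  a0 <- dfa(x)$alpha
  expect_equal(dfa(5 * x + 100)$alpha, a0, tolerance = 1e-10)
  expect_equal(dfa(-x)$alpha, a0, tolerance = 1e-12)
})

test_that("dfa separates the canonical correlation classes at moderate length", {
  # reduced-N spot checks; the full N = 65536 versions run in the acceptance suite
  a_white <- mean(vapply(1:5, function(s) {
    set.seed(s); dfa(rnorm(16384))$alpha
  }, numeric(1)))
  expect_lt(abs(a_white - 0.5), 0.04)
  a_walk <- { set.seed(1); dfa(cumsum(rnorm(16384)))$alpha }
  expect_gt(a_walk, 1)
  expect_lt(dfa(generate_fgn(0.2, 16384, seed = 2))$alpha, 0.5)
})
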