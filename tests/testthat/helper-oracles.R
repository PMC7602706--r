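# Independent, deliberately naive reference implementations used as oracles.
# These mirror the algorithm definitions directly (explicit loops, lm() fits)
# and stay independent of the package's vectorized / compiled code paths.

naive_profile <- function(x) {
  m <- sum(x) / length(x)
  y <- numeric(length(x))
  acc <- 0
  for (i in seq_along(x)) {
    acc <- acc + (x[i] - m)
    y[i] <- acc
  }
  y
}

naive_fluct <- function(profile, scales, order) {
  N <- length(profile)
  vapply(scales, function(n) {
    m <- N %/% n
    ss <- 0
    for (s in seq_len(m)) {
      seg <- profile[((s - 1) * n + 1):(s * n)]
      t <- seq_len(n)
      fit <- if (order == 0) lm(seg ~ 1)
             else lm(seg ~ poly(t, order, raw = TRUE))
      ss <- ss + sum(residuals(fit)^2)
    }
    sqrt(ss / (m * n))
  }, numeric(1))
}

naive_ols <- function(x, y) {
  # closed-form simple regression slope and intercept
  xm <- mean(x); ym <- mean(y)
  b <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  c(intercept = ym - b * xm, slope = b)
}

# exact two-sided Mann-Whitney p by full enumeration of label assignments
enum_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# small step-H test signal: first half H_lo, second half H_hi
step_h_signal <- function(H_lo, H_hi, dur_s = 10, fs = 250, seed = 1) {
  pr <- hurst_profile(c(0, dur_s), c(dur_s, 2 * dur_s), c(H_lo, H_hi),
                      crossfade_s = 0.5)
  generate_modulated_signal(pr, fs, seed = seed)
}

# tiny cohort spec used across tests (single analysed channel)
tiny_spec <- function(seed, n_subjects = 2, trials = 3,
                      channels = "C4", gains = c(C4 = 1), ...) {
  cohort_spec(n_subjects = n_subjects, trials_per_hand = trials,
              trials_kept_per_hand = trials, channels = channels,
              channel_gain = gains, seed = seed, ...)
}
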