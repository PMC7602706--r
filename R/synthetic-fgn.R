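#' Autocovariance of fractional Gaussian noise
#'
#' Closed form `gamma(k) = 0.5 * (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})` for
#' unit-variance fGn with Hurst exponent `H`.
#'
#' @param H Hurst exponent in (0, 1).
#' @param lags integer lags (>= 0).
#' @return numeric vector of autocovariances.
#' @export
fgn_autocov <- function(H, lags) {
  stopifnot(H > 0, H < 1)
  k <- abs(as.numeric(lags))
  0.5 * (abs(k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
}

#' Simulate fractional Gaussian noise
#'
#' Exact circulant-embedding (Davies-Harte) synthesis of a stationary,
#' unit-variance Gaussian sequence with the fGn autocovariance.  The
#' embedding is provably non-negative definite for fGn, but a guarded
#' spectral-approximation fallback is kept for numerically pathological
#' `H` / `N` combinations (a message is emitted if it ever triggers).
#'
#' @param H Hurst exponent in (0, 1).  `H = 0.5` gives white noise; DFA on
#'   fGn yields a scaling exponent `alpha = H`.
#' @param N length (>= 2).
#' @param seed integer seed for reproducibility; `NULL` uses the current RNG
#'   stream.
#' @return numeric vector of length `N`.
#' @export
#' @examples
#' x <- generate_fgn(0.75, 1024, seed = 1)
generate_fgn <- function(H, N, seed = NULL) {
  stopifnot(H > 0, H < 1, N >= 2)
  with_seed(seed, {
    m <- 2L * N
    g <- fgn_autocov(H, 0:N)
    row <- c(g, g[N:2])                    # circulant first row, length 2N
    lam <- Re(fft(row))
    tol <- 1e-8 * max(lam)
    lam[lam < 0 & lam > -tol] <- 0
    if (any(lam < 0)) {
      message("circulant embedding not non-negative definite; ",
              "using spectral approximation")
      return(fgn_spectral_approx(H, N))
    }
    Z <- complex(length.out = m)
    Z[1] <- sqrt(lam[1]) * rnorm(1)
    Z[N + 1] <- sqrt(lam[N + 1]) * rnorm(1)
    u <- rnorm(N - 1)
    v <- rnorm(N - 1)
    Z[2:N] <- sqrt(lam[2:N] / 2) * complex(real = u, imaginary = v)
    Z[m:(N + 2)] <- Conj(Z[2:N])
    x <- Re(fft(Z, inverse = TRUE)) / sqrt(m)
    x[seq_len(N)]
  })
}

# approximate synthesis from the fGn spectral density (fallback only)
fgn_spectral_approx <- function(H, N) {
  m <- 2L * N
  f <- seq_len(m %/% 2) / m
  S <- f^(1 - 2 * H)                       # power-law spectral shape
  amp <- sqrt(S)
  ph <- runif(length(f), 0, 2 * pi)
  spec <- complex(length.out = m)
  spec[2:(length(f) + 1)] <- amp * exp(1i * ph)
  spec[m:(m - length(f) + 2)] <- Conj(spec[2:length(f)])
  x <- Re(fft(spec, inverse = TRUE))
  x <- x[seq_len(N)]
  (x - mean(x)) / sd(x)
}

#' Piecewise Hurst-exponent profile
#'
#' Describes a target scaling-exponent timecourse as contiguous segments of
#' constant `H`, joined by equal-power raised-cosine crossfades of length
#' `crossfade_s` centred on the segment boundaries.
#'
#' @param t_start_s,t_end_s,H equal-length vectors: segment bounds in
#'   seconds (contiguous, non-overlapping) and Hurst targets in (0, 1).
#' @param crossfade_s crossfade length in seconds (default 0.5); must not
#'   exceed the shortest segment duration.
#' @return object of class `hurst_profile` (data frame plus `crossfade_s`
#'   attribute).
#' @export
hurst_profile <- function(t_start_s, t_end_s, H, crossfade_s = 0.5) {
  stopifnot(length(t_start_s) == length(t_end_s),
            length(H) == length(t_start_s), length(H) >= 1)
  if (any(t_end_s <= t_start_s)) stop("segments must have positive duration")
  if (length(H) > 1 && any(abs(t_start_s[-1] - t_end_s[-length(t_end_s)]) > 1e-9))
    stop("segments must be contiguous")
  if (any(H <= 0 | H >= 1)) stop("H must lie in (0, 1)")
  if (crossfade_s < 0) stop("crossfade_s must be non-negative")
  if (crossfade_s > min(t_end_s - t_start_s))
    stop("crossfade longer than the shortest segment")
  out <- data.frame(t_start_s = t_start_s, t_end_s = t_end_s, H = H)
  attr(out, "crossfade_s") <- crossfade_s
  class(out) <- c("hurst_profile", "data.frame")
  out
}

#' Nominal Hurst timecourse of a profile
#'
#' Power-weighted target exponent at arbitrary times: constant inside
#' segments, raised-cosine interpolation (`cos^2` / `sin^2` power weights)
#' across crossfades.
#'
#' @param profile a `hurst_profile`.
#' @param times_s numeric times in seconds.
#' @return numeric vector of target H values.
#' @export
hurst_timecourse <- function(profile, times_s) {
  xf <- attr(profile, "crossfade_s")
  nseg <- nrow(profile)
  H <- numeric(length(times_s))
  seg_of <- findInterval(times_s, c(profile$t_start_s, profile$t_end_s[nseg]),
                         all.inside = TRUE)
  H <- profile$H[seg_of]
  if (xf > 0 && nseg > 1) {
    for (b in seq_len(nseg - 1)) {
      tb <- profile$t_end_s[b]
      inx <- times_s > tb - xf / 2 & times_s < tb + xf / 2
      if (!any(inx)) next
      u <- (times_s[inx] - (tb - xf / 2)) / xf     # 0..1 across the fade
      w2 <- sin(pi * u / 2)^2
      H[inx] <- (1 - w2) * profile$H[b] + w2 * profile$H[b + 1]
    }
  }
  H
}

#' Signal with a time-varying scaling exponent
#'
#' Synthesizes a unit-variance Gaussian signal whose local correlation
#' structure follows a piecewise Hurst profile: one independent fGn process
#' per segment, joined by equal-power raised-cosine crossfades (amplitude
#' weights `cos`, `sin` over the fade, so the variance is preserved).
#' Sliding-window DFA of the output tracks the profile, lagged and smoothed
#' by the analysis window.
#'
#' @param profile a `hurst_profile`.
#' @param sampling_rate sampling rate in Hz.
#' @param seed integer seed; `NULL` uses the current stream.
#' @return numeric vector covering the full profile span, with attributes
#'   `sampling_rate` and `profile`.
#' @export
generate_modulated_signal <- function(profile, sampling_rate, seed = NULL) {
  stopifnot(inherits(profile, "hurst_profile"), sampling_rate > 0)
  xf <- attr(profile, "crossfade_s")
  nseg <- nrow(profile)
  t0 <- profile$t_start_s[1]
  t1 <- profile$t_end_s[nseg]
  N <- round((t1 - t0) * sampling_rate)
  nxf <- round(xf * sampling_rate)
  with_seed(seed, {
    out <- numeric(N)
    # sample index ranges per segment, extended by half a crossfade each side
    for (s in seq_len(nseg)) {
      a0 <- round((profile$t_start_s[s] - t0) * sampling_rate) -
        (if (s > 1) nxf %/% 2 else 0)
      a1 <- round((profile$t_end_s[s] - t0) * sampling_rate) +
        (if (s < nseg) nxf - nxf %/% 2 else 0)
      a0 <- max(0L, a0); a1 <- min(N, a1)
      len <- a1 - a0
      if (len <= 1) next
      x <- generate_fgn(profile$H[s], len)
      w <- rep(1, len)
      if (s > 1 && nxf > 0) {
        u <- (seq_len(min(nxf, len)) - 0.5) / nxf
        w[seq_along(u)] <- sin(pi * u / 2)     # fade in
      }
      if (s < nseg && nxf > 0) {
        u <- (seq_len(min(nxf, len)) - 0.5) / nxf
        w[len - length(u) + seq_along(u)] <- w[len - length(u) + seq_along(u)] *
          cos(pi * u / 2)                      # fade out
      }
      out[(a0 + 1):a1] <- out[(a0 + 1):a1] + w * x
    }
    attr(out, "sampling_rate") <- sampling_rate
    attr(out, "profile") <- profile
    out
  })
}
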