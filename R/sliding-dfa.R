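#' Time-resolved scaling exponent via a floating window
#'
#' Applies DFA to successive windowed excerpts of a signal, producing the
#' trajectory alpha(t).  Each window is analysed in isolation (profile built
#' from the mean-centred excerpt), so the value at each position equals
#' [dfa()] applied to that excerpt with the same scale grid and full-grid fit
#' range.
#'
#' @param x numeric signal (one channel).
#' @param sampling_rate sampling rate in Hz.
#' @param window_len window length W in samples (default 500, i.e. 2 s at
#'   250 Hz).  Values below 100 trigger a warning: short windows restrict the
#'   usable scale range and inflate the fit error.
#' @param step window step in samples (default 25, 0.1 s at 250 Hz).
#' @param anchor time convention for attributing alpha to the window:
#'   `"center"` (default), `"start"`, or `"end"`.
#' @param detrend_order polynomial detrending order (default 1).
#' @param n_min,n_max,n_scales per-window scale grid; the default grid spans
#'   `[8, min(125, floor(W / 4))]` with 10 log-spaced points, i.e.
#'   `lg n` up to about 2.1 for the default 500-sample window.
#' @param t0 time (seconds) of the first sample of `x`; use e.g. `-pre_s` for
#'   an epoch so that trajectory times are relative to the event onset.
#' @return an object of class `alpha_trajectory`: list with `times` (anchor
#'   times, seconds), `alphas`, `window_len`, `step`, `anchor`,
#'   `sampling_rate`, and `dfa_params`.
#' @export
sliding_alpha <- function(x, sampling_rate, window_len = 500, step = 25,
                          anchor = c("center", "start", "end"),
                          detrend_order = 1, n_min = 8,
                          n_max = min(125L, window_len %/% 4L),
                          n_scales = 10, t0 = 0) {
  anchor <- match.arg(anchor)
  x <- as.numeric(x)
  N <- length(x)
  stopifnot(sampling_rate > 0, step >= 1, window_len >= 8)
  if (window_len > N) stop("window_len exceeds signal length")
  if (window_len < 100)
    warning("window_len < 100 samples: scaling fits will be noisy")
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  scales <- dfa_scales(window_len, n_min = n_min, n_max = n_max,
                       n_scales = n_scales)
  alphas <- sliding_alpha_cpp(x, as.integer(window_len), as.integer(step),
                              scales, as.integer(detrend_order))
  starts <- seq(0L, N - window_len, by = step) # 0-based start sample
  offset <- switch(anchor,
                   start  = 0,
                   center = window_len / 2,
                   end    = window_len)
  times <- t0 + (starts + offset) / sampling_rate
  structure(
    list(times = times, alphas = as.numeric(alphas),
         window_len = as.integer(window_len), step = as.integer(step),
         anchor = anchor, sampling_rate = sampling_rate,
         dfa_params = list(scales = scales, detrend_order = detrend_order,
                           fit_range = range(log10(scales)))),
    class = "alpha_trajectory"
  )
}

#' @export
print.alpha_trajectory <- function(x, ...) {
  cat(sprintf("alpha(t) trajectory: %d windows of %d samples (step %d, %s anchor), t in [%.2f, %.2f] s\n",
              length(x$times), x$window_len, x$step, x$anchor,
              min(x$times), max(x$times)))
  invisible(x)
}

#' Smoothness diagnostic for an alpha trajectory
#'
#' Reports the maximum absolute first difference of alpha(t).  On identical
#' inputs, larger analysis windows act as stronger low-pass filters of
#' alpha(t) and yield smaller maximum jumps.
#'
#' @param traj an `alpha_trajectory` with at least 3 points.
#' @return list with `max_jump`, `mean_jump` and `n` (number of differences).
#' @export
trajectory_smoothness <- function(traj) {
  stopifnot(inherits(traj, "alpha_trajectory"))
  a <- traj$alphas[is.finite(traj$alphas)]
  if (length(a) < 3L) stop("need at least 3 finite trajectory points")
  d <- abs(diff(a))
  list(max_jump = max(d), mean_jump = mean(d), n = length(d))
}
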