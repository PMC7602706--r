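#' Log-spaced scale grid for DFA
#'
#' Builds a strictly increasing grid of integer segment lengths, approximately
#' equidistant in log10, for use with [fluctuation_function()].
#'
#' @param N signal length in samples.
#' @param n_min smallest scale (default 8; must allow at least
#'   `detrend_order + 2` samples per segment).
#' @param n_max largest scale; defaults to `floor(N / 4)` so that the largest
#'   scale still averages at least four segments.
#' @param n_scales requested number of grid points (default 12); duplicates
#'   arising from rounding are dropped.
#' @return integer vector of scales, each `<= floor(N / 2)`.
#' @export
#' @examples
#' dfa_scales(1000)
dfa_scales <- function(N, n_min = 8, n_max = NULL, n_scales = 12) {
  stopifnot(N >= 4, n_min >= 2)
  if (is.null(n_max)) n_max <- floor(N / 4)
  n_max <- max(n_min, n_max)
  s <- unique(round(10^seq(log10(n_min), log10(n_max), length.out = n_scales)))
  s <- as.integer(s[s <= floor(N / 2)])
  if (length(s) == 0L) stop("no admissible scales: signal too short for n_min = ", n_min)
  s
}

#' Profile (integrated, mean-centred signal) for DFA
#'
#' The random-walk representation y(k) = sum_{i<=k} (x_i - mean(x)); its last
#' element is zero up to rounding.
#'
#' @param x numeric vector, length >= 2, all finite.
#' @return numeric vector of the same length as `x`.
#' @export
#' @examples
#' build_profile(c(1, 2, 3)) # -1 -1 0
build_profile <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("signal must contain at least 2 samples")
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  cumsum(x - mean(x))
}

#' Detrended fluctuation function F(n)
#'
#' Cuts the profile into `floor(N / n)` non-overlapping segments from the
#' start, removes a least-squares polynomial trend of order `detrend_order`
#' from each, and returns the RMS residual over the covered samples for every
#' scale `n`.  Trailing samples not filling a complete segment are discarded
#' and the normalization uses the covered sample count.
#'
#' @param profile numeric vector as returned by [build_profile()].
#' @param scales strictly increasing positive integers, each within
#'   `[detrend_order + 2, floor(N / 2)]`.
#' @param detrend_order polynomial detrending order (default 1, piecewise
#'   linear).
#' @return an object of class `fluctuation_curve`: list with `scales`,
#'   `fluctuations`, `detrend_order`.
#' @export
fluctuation_function <- function(profile, scales, detrend_order = 1) {
  profile <- as.numeric(profile)
  N <- length(profile)
  if (!all(is.finite(profile))) stop("profile contains non-finite values")
  scales <- as.integer(scales)
  if (length(scales) == 0L) stop("empty scale grid")
  if (any(diff(scales) <= 0L)) stop("scales must be strictly increasing")
  if (any(scales < detrend_order + 2L))
    stop("scales must be at least detrend_order + 2")
  if (any(scales > N %/% 2L))
    stop("scales must not exceed floor(N / 2) = ", N %/% 2L)
  stopifnot(detrend_order >= 0L)
  F <- dfa_fluct_cpp(profile, scales, as.integer(detrend_order))
  structure(
    list(scales = scales, fluctuations = as.numeric(F),
         detrend_order = as.integer(detrend_order)),
    class = "fluctuation_curve"
  )
}

#' @export
print.fluctuation_curve <- function(x, ...) {
  cat("DFA fluctuation curve:", length(x$scales), "scales, detrend order",
      x$detrend_order, "\n")
  print(data.frame(n = x$scales, F = x$fluctuations), row.names = FALSE)
  invisible(x)
}

#' Fit the scaling exponent alpha
#'
#' Least-squares slope of lg F(n) versus lg n restricted to `fit_range`
#' (base-10 logarithms throughout).  Scales with `F(n) == 0` are excluded with
#' a warning; at least three usable points are required, except for the fully
#' degenerate curve (all fluctuations zero, e.g. a constant signal) which
#' yields `alpha = NaN`.
#'
#' @param curve a `fluctuation_curve`.
#' @param fit_range numeric length-2, `c(lg_n_min, lg_n_max)`; `NULL` (default)
#'   uses the full scale range of the curve.
#' @return an object of class `scaling_fit`: list with `alpha`, `intercept`,
#'   `fit_range`, `residual_rms`, `n_points`.
#' @export
fit_scaling_exponent <- function(curve, fit_range = NULL) {
  stopifnot(inherits(curve, "fluctuation_curve"))
  lg_n <- log10(curve$scales)
  if (is.null(fit_range)) fit_range <- range(lg_n)
  stopifnot(length(fit_range) == 2L, fit_range[1] <= fit_range[2])
  tol <- 1e-9
  in_range <- lg_n >= fit_range[1] - tol & lg_n <= fit_range[2] + tol
  F <- curve$fluctuations
  usable <- in_range & is.finite(F) & F > 0
  if (!any(is.finite(F[in_range]) & F[in_range] > 0)) {
    if (all(F[in_range] == 0, na.rm = TRUE) && any(in_range)) {
      warning("all fluctuations are zero in the fit range; alpha undefined")
      return(structure(list(alpha = NaN, intercept = NaN,
                            fit_range = fit_range, residual_rms = NaN,
                            n_points = 0L),
                       class = "scaling_fit"))
    }
    stop("no usable scales in fit range")
  }
  if (any(in_range & is.finite(F) & F == 0))
    warning("excluding ", sum(in_range & F == 0, na.rm = TRUE),
            " scale(s) with F(n) = 0 from the fit")
  if (sum(usable) < 3L)
    stop("fewer than 3 usable scales in fit range")
  lx <- lg_n[usable]
  ly <- log10(F[usable])
  fit <- lm.fit(cbind(1, lx), ly)
  res <- fit$residuals
  structure(
    list(alpha = unname(fit$coefficients[2]),
         intercept = unname(fit$coefficients[1]),
         fit_range = as.numeric(fit_range),
         residual_rms = sqrt(mean(res^2)),
         n_points = as.integer(sum(usable))),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("DFA scaling fit: alpha = %.4f (lg n in [%.2f, %.2f], %d points, residual RMS %.3g)\n",
              x$alpha, x$fit_range[1], x$fit_range[2], x$n_points, x$residual_rms))
  invisible(x)
}

#' Detrended fluctuation analysis of a signal
#'
#' Composition of [build_profile()], [fluctuation_function()] and
#' [fit_scaling_exponent()].
#'
#' @param x numeric signal.
#' @param scales integer scale grid; `NULL` (default) uses
#'   [dfa_scales()] with the given `n_min` / `n_max` / `n_scales`.
#' @param detrend_order polynomial detrending order (default 1).
#' @param fit_range `c(lg_n_min, lg_n_max)`.  `NULL` (default) selects
#'   `[1.2, lg n_max]` when the grid extends beyond `lg n = 1.5` (the
#'   convention for full-length recordings) and the full grid otherwise
#'   (short windowed excerpts).
#' @param n_min,n_max,n_scales passed to [dfa_scales()] when `scales` is
#'   `NULL`.
#' @param return_curve if `TRUE`, attach the fluctuation curve to the result
#'   as attribute `"curve"`.
#' @return a `scaling_fit`.
#' @export
#' @examples
#' set.seed(1)
#' dfa(rnorm(4096))$alpha # about 0.5
dfa <- function(x, scales = NULL, detrend_order = 1, fit_range = NULL,
                n_min = 8, n_max = NULL, n_scales = 12, return_curve = FALSE) {
  prof <- build_profile(x)
  if (is.null(scales))
    scales <- dfa_scales(length(prof), n_min = n_min, n_max = n_max,
                         n_scales = n_scales)
  curve <- fluctuation_function(prof, scales, detrend_order = detrend_order)
  if (is.null(fit_range)) {
    lg_max <- log10(max(scales))
    fit_range <- if (lg_max >= 1.5) c(1.2, lg_max) else range(log10(scales))
  }
  fit <- fit_scaling_exponent(curve, fit_range)
  if (return_curve) attr(fit, "curve") <- curve
  fit
}
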