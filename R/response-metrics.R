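#' Normalize an alpha(t) segment to its starting value
#'
#' Selects the trajectory points with times in `[t_start_s, t_end_s]` and
#' divides them by the alpha value at the grid point nearest `t_start_s`, so
#' the response starts at exactly 1.0.  Normalization is applied per trial,
#' before any averaging.
#'
#' @param traj an `alpha_trajectory`.
#' @param t_start_s,t_end_s segment bounds in trajectory time (seconds).
#' @param segment optional label, e.g. `"clench"` or `"unclench"`.
#' @return object of class `normalized_response`: list with `times` (relative
#'   to the reference grid point), `values` (first element exactly 1),
#'   `segment`, `ref_alpha`.
#' @export
normalize_segment <- function(traj, t_start_s, t_end_s, segment = NA_character_) {
  stopifnot(inherits(traj, "alpha_trajectory"), t_end_s > t_start_s)
  tol <- 1e-9
  if (t_start_s < min(traj$times) - tol || t_end_s > max(traj$times) + tol)
    stop("segment bounds outside the trajectory")
  i0 <- which.min(abs(traj$times - t_start_s))
  ref <- traj$alphas[i0]
  if (!is.finite(ref) || ref <= 0)
    stop("alpha at segment start is missing or non-positive")
  sel <- which(traj$times >= traj$times[i0] - tol & traj$times <= t_end_s + tol)
  structure(
    list(times = traj$times[sel] - traj$times[i0],
         values = traj$alphas[sel] / ref,
         segment = segment, ref_alpha = ref),
    class = "normalized_response"
  )
}

#' Response slope r = d(alpha)/dt
#'
#' Ordinary least-squares slope of the normalized alpha values versus time
#' (in seconds) over `fit_interval_s`, with its OLS standard error.
#'
#' @param resp a `normalized_response` (or a `group_curve`; any list with
#'   `times` and `values` or `mean`).
#' @param fit_interval_s numeric length-2 interval in segment-relative
#'   seconds; default `c(0, 2)`.
#' @return object of class `slope_estimate`: list with `r`, `stderr`,
#'   `fit_interval_s`, `n_points`.
#' @export
estimate_slope <- function(resp, fit_interval_s = c(0, 2)) {
  stopifnot(length(fit_interval_s) == 2L,
            fit_interval_s[1] < fit_interval_s[2])
  vals <- if (!is.null(resp$values)) resp$values else resp$mean
  if (is.null(vals)) stop("resp must carry 'values' or 'mean'")
  tol <- 1e-9
  sel <- resp$times >= fit_interval_s[1] - tol &
         resp$times <= fit_interval_s[2] + tol &
         is.finite(vals)
  t <- resp$times[sel]
  v <- vals[sel]
  n <- length(t)
  if (n < 3L) stop("need at least 3 points inside the fit interval")
  tm <- t - mean(t)
  sxx <- sum(tm^2)
  slope <- sum(tm * v) / sxx
  res <- v - mean(v) - slope * tm
  s2 <- sum(res^2) / (n - 2)
  structure(
    list(r = slope, stderr = sqrt(s2 / sxx),
         fit_interval_s = as.numeric(fit_interval_s), n_points = n),
    class = "slope_estimate"
  )
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("slope r = %.4f / s (SE %.4f, %d points, fit [%g, %g] s)\n",
              x$r, x$stderr, x$n_points, x$fit_interval_s[1],
              x$fit_interval_s[2]))
  invisible(x)
}

check_common_grid <- function(responses) {
  t0 <- responses[[1]]$times
  for (r in responses[-1])
    if (length(r$times) != length(t0) || max(abs(r$times - t0)) > 1e-8)
      stop("responses are not on a common time grid")
  t0
}

#' Average normalized responses over trials (subject level)
#'
#' Pointwise mean of per-trial normalized responses on a common time grid,
#' with the standard error across trials.
#'
#' @param responses list of `normalized_response` objects with identical
#'   grids.
#' @return object of class `group_curve` (`level = "subject"`): list with
#'   `times`, `mean`, `se`, `n`, `level`.
#' @export
average_trials <- function(responses) {
  stopifnot(length(responses) >= 1L)
  t0 <- check_common_grid(responses)
  M <- vapply(responses, function(r) r$values, numeric(length(t0)))
  M <- matrix(M, nrow = length(t0))
  n <- ncol(M)
  structure(
    list(times = t0, mean = rowMeans(M),
         se = if (n > 1) apply(M, 1, sd) / sqrt(n) else rep(NA_real_, length(t0)),
         n = n, level = "subject"),
    class = "group_curve"
  )
}

#' Average subject curves into a group curve
#'
#' Pointwise mean across subjects with standard error `sd / sqrt(n)`.  This
#' is the second stage of the double averaging (trials within subject, then
#' subjects within group); with unequal trial counts, subjects are weighted
#' equally.
#'
#' @param curves list of subject-level `group_curve` objects on a common
#'   grid.
#' @return object of class `group_curve` (`level = "group"`); with a single
#'   subject the SE is `NA` (flagged undefined).
#' @export
average_subjects <- function(curves) {
  stopifnot(length(curves) >= 1L)
  t0 <- check_common_grid(curves)
  M <- vapply(curves, function(cu) cu$mean, numeric(length(t0)))
  M <- matrix(M, nrow = length(t0))
  n <- ncol(M)
  if (n == 1L)
    warning("single subject: group SE undefined")
  structure(
    list(times = t0, mean = rowMeans(M),
         se = if (n > 1) apply(M, 1, sd) / sqrt(n) else rep(NA_real_, length(t0)),
         n = n, level = "group"),
    class = "group_curve"
  )
}

#' Left-vs-right-hand response contrast
#'
#' For every subject x channel with both hands present, computes the signed
#' (`r_LH - r_RH`) and absolute LH-RH slope difference, averages over
#' channels within subject, and summarizes across the group as mean and
#' standard error.  Subject/channel combinations missing a hand are excluded
#' with a warning.
#'
#' @param slopes data frame with columns `subject`, `channel`, `hand`
#'   (`"LH"`/`"RH"`), `r`.
#' @return list with `per_subject` (data frame: subject, mean signed and
#'   absolute channel-averaged difference), `mean_abs`, `se_abs`,
#'   `mean_signed`, `se_signed`, `n_subjects`.
#' @export
lh_rh_contrast <- function(slopes) {
  slopes <- as.data.frame(slopes)
  stopifnot(all(c("subject", "channel", "hand", "r") %in% names(slopes)))
  key <- interaction(slopes$subject, slopes$channel, drop = TRUE)
  rows <- split(seq_len(nrow(slopes)), key)
  rec <- list()
  dropped <- 0L
  for (idx in rows) {
    s <- slopes[idx, ]
    r_lh <- s$r[s$hand == "LH"]
    r_rh <- s$r[s$hand == "RH"]
    if (length(r_lh) != 1L || length(r_rh) != 1L) {
      dropped <- dropped + 1L
      next
    }
    rec[[length(rec) + 1L]] <- data.frame(
      subject = s$subject[1], channel = s$channel[1],
      signed = r_lh - r_rh, abs = abs(r_lh - r_rh))
  }
  if (dropped > 0L)
    warning(dropped, " subject/channel combination(s) missing a hand; excluded")
  if (length(rec) == 0L) stop("no subject/channel with both hands present")
  d <- do.call(rbind, rec)
  per_subj <- aggregate(d[c("signed", "abs")], by = list(subject = d$subject),
                        FUN = mean)
  n <- nrow(per_subj)
  list(per_subject = per_subj,
       mean_abs = mean(per_subj$abs),
       se_abs = if (n > 1) sd(per_subj$abs) / sqrt(n) else NA_real_,
       mean_signed = mean(per_subj$signed),
       se_signed = if (n > 1) sd(per_subj$signed) / sqrt(n) else NA_real_,
       n_subjects = n)
}
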