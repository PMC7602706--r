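#' Multichannel recording container
#'
#' A light-weight container for a sample matrix (time x channels, microvolts),
#' its sampling rate, and unique channel labels (10-10 system names for EEG).
#'
#' @param samples numeric matrix, rows = time points, columns = channels.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_labels character vector of unique labels, one per column.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sampling_rate, channel_labels = colnames(samples)) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(ncol(samples)))
  channel_labels <- as.character(channel_labels)
  stopifnot(sampling_rate > 0, length(channel_labels) == ncol(samples))
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  colnames(samples) <- channel_labels
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channel_labels = channel_labels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("eeg_recording: %d samples x %d channels at %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              nrow(x$samples) / x$sampling_rate))
  cat("channels:", paste(x$channel_labels, collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$samples)

# --- digital Butterworth design (bilinear transform) ------------------------

poly_from_roots <- function(r) {
  co <- 1 + 0i
  for (ri in r) co <- c(co, 0 + 0i) - ri * c(0 + 0i, co)
  co
}

polyval_c <- function(co, z) {
  v <- 0 + 0i
  for (c1 in co) v <- v * z + c1
  v
}

#' Butterworth filter coefficients
#'
#' Designs a digital Butterworth low- or high-pass filter of the given order
#' via analog prototype pole placement and the bilinear transform, returning
#' transfer-function coefficients normalized to `a[1] = 1`.
#'
#' @param order filter order (poles).
#' @param cutoff_hz -3 dB cutoff frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param type `"low"` or `"high"`.
#' @return list with numeric vectors `b` and `a`.
#' @export
butter_coeffs <- function(order, cutoff_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(order >= 1, cutoff_hz > 0, cutoff_hz < fs / 2)
  k <- seq_len(order)
  p_proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # left half-plane
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)                     # pre-warped
  if (type == "low") {
    s_poles <- wc * p_proto
    z_zeros <- rep(-1 + 0i, order)
    zref <- 1 + 0i
  } else {
    s_poles <- wc / p_proto
    z_zeros <- rep(1 + 0i, order)
    zref <- -1 + 0i
  }
  z_poles <- (2 * fs + s_poles) / (2 * fs - s_poles)
  a <- Re(poly_from_roots(z_poles))
  b <- Re(poly_from_roots(z_zeros))
  g <- Re(polyval_c(as.complex(a), zref) / polyval_c(as.complex(b), zref))
  list(b = g * b / a[1], a = a / a[1])
}

#' Notch (band-reject) biquad coefficients
#'
#' Second-order IIR notch with centre frequency `freq_hz` and quality factor
#' `q` (bandwidth `freq_hz / q`).
#'
#' @param freq_hz notch centre frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param q quality factor (default 30).
#' @return list with numeric vectors `b` and `a`.
#' @export
notch_coeffs <- function(freq_hz, fs, q = 30) {
  stopifnot(freq_hz > 0, freq_hz < fs / 2, q > 0)
  w0 <- 2 * pi * freq_hz / fs
  al <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + al, -2 * cos(w0), 1 - al)
  list(b = b / a[1], a = a / a[1])
}

#' Zero-phase IIR filtering
#'
#' Applies the filter forward and backward (squared magnitude response, zero
#' phase), with odd-reflection padding at both ends to suppress edge
#' transients.
#'
#' @param b,a transfer-function coefficients (`a[1]` is normalized to 1).
#' @param x numeric vector.
#' @param padlen padding length in samples; default
#'   `3 * (max(length(a), length(b)) - 1)`, capped at `length(x) - 1`.
#' @return filtered numeric vector, same length as `x`.
#' @export
filtfilt_ba <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- 3 * (max(length(a), length(b)) - 1)
  padlen <- max(0L, min(n - 1L, as.integer(padlen)))
  b <- b / a[1]; a <- a / a[1]
  xp <- if (padlen > 0)
    c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  else x
  y <- iir_filter_cpp(b, a, xp)
  y <- rev(iir_filter_cpp(b, a, rev(y)))
  if (padlen > 0) y[(padlen + 1):(padlen + n)] else y
}

filter_channels <- function(x, fun) {
  if (inherits(x, "eeg_recording")) {
    x$samples <- apply(x$samples, 2, fun)
    return(x)
  }
  if (is.matrix(x)) return(apply(x, 2, fun))
  fun(as.numeric(x))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Band-limits every channel with a cascade of an order-`order` high-pass at
#' `low_hz` and an order-`order` low-pass at `high_hz`, each applied
#' forward-backward (zero phase).
#'
#' @param x an `eeg_recording`, a numeric matrix (time x channels), or a
#'   numeric vector.
#' @param low_hz,high_hz band edges in Hz; `0 < low_hz < high_hz < fs / 2`.
#' @param order Butterworth order of each cascade stage (default 4).
#' @param sampling_rate required when `x` is not an `eeg_recording`.
#' @return object of the same kind as `x`, filtered.
#' @export
bandpass_filter <- function(x, low_hz = 1, high_hz = 100, order = 4,
                            sampling_rate = NULL) {
  fs <- if (inherits(x, "eeg_recording")) x$sampling_rate else sampling_rate
  if (is.null(fs)) stop("sampling_rate is required for plain numeric input")
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop("need 0 < low_hz < high_hz < Nyquist = ", fs / 2, " Hz")
  hp <- butter_coeffs(order, low_hz, fs, "high")
  lp <- butter_coeffs(order, high_hz, fs, "low")
  # generous padding: high-pass transients decay on the 1/low_hz time scale
  padlen <- round(3 * fs / low_hz)
  filter_channels(x, function(v) {
    v <- filtfilt_ba(hp$b, hp$a, v, padlen = padlen)
    filtfilt_ba(lp$b, lp$a, v, padlen = padlen)
  })
}

#' Zero-phase notch filter
#'
#' Narrow band-rejection (e.g. 50 Hz mains) applied forward-backward on every
#' channel.
#'
#' @inheritParams bandpass_filter
#' @param freq_hz notch centre frequency in Hz (default 50).
#' @param q quality factor (default 30).
#' @return object of the same kind as `x`, filtered.
#' @export
notch_filter <- function(x, freq_hz = 50, q = 30, sampling_rate = NULL) {
  fs <- if (inherits(x, "eeg_recording")) x$sampling_rate else sampling_rate
  if (is.null(fs)) stop("sampling_rate is required for plain numeric input")
  if (!(freq_hz > 0 && freq_hz < fs / 2))
    stop("notch frequency outside (0, Nyquist)")
  co <- notch_coeffs(freq_hz, fs, q)
  padlen <- round(3 * fs * q / freq_hz)
  filter_channels(x, function(v) filtfilt_ba(co$b, co$a, v, padlen = padlen))
}

# --- events and epochs ------------------------------------------------------

#' Event table constructor / validator
#'
#' One row per motor task: onset of the first audio cue, hand label, cue
#' duration, optional second-cue (unclench) time and keep flag.
#'
#' @param onset_s first-cue onsets in seconds from recording start, strictly
#'   increasing.
#' @param hand `"LH"` or `"RH"` per trial.
#' @param cue_duration_s audio cue duration in seconds.
#' @param unclench_s second-cue (unclench) time; defaults to
#'   `onset_s + 4.5` (middle of the 4-5 s active-phase range).
#' @param keep logical keep/drop mask modelling manual artifact rejection
#'   (default all `TRUE`).
#' @return validated `data.frame` with class `event_table`.
#' @export
event_table <- function(onset_s, hand, cue_duration_s,
                        unclench_s = onset_s + 4.5, keep = TRUE) {
  onset_s <- as.numeric(onset_s)
  hand <- as.character(hand)
  n <- length(onset_s)
  stopifnot(n >= 1, length(hand) == n)
  if (any(diff(onset_s) <= 0)) stop("event onsets must be strictly increasing")
  if (!all(hand %in% c("LH", "RH"))) stop("hand must be 'LH' or 'RH'")
  ev <- data.frame(onset_s = onset_s, hand = hand,
                   cue_duration_s = rep_len(as.numeric(cue_duration_s), n),
                   unclench_s = rep_len(as.numeric(unclench_s), n),
                   keep = rep_len(as.logical(keep), n))
  if (any(ev$unclench_s <= ev$onset_s)) stop("unclench_s must exceed onset_s")
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Extract event-aligned epochs
#'
#' Cuts one fixed-length epoch per event, `pre_s` seconds before to `post_s`
#' seconds after the first-cue onset (half-open sample interval, 0-based index
#' arithmetic: samples `[round(onset * fs) - round(pre_s * fs),
#' + round((pre_s + post_s) * fs))`).  Events whose epoch would leave the
#' recording are skipped with a warning.  Rows with `keep == FALSE` are
#' dropped when `use_keep` is `TRUE`.
#'
#' @param rec an `eeg_recording`.
#' @param events an `event_table` (or compatible data frame).
#' @param pre_s,post_s epoch extent in seconds around the onset (defaults 2
#'   and 12, spanning baseline, active phase, unclench and pause).
#' @param use_keep honour the `keep` column (default `TRUE`).
#' @return list of `task_epoch` objects; each has `samples`, `sampling_rate`,
#'   `channel_labels`, `t0_offset_s` (= `pre_s`), `hand`, `trial`, `onset_s`,
#'   `unclench_s`, `cue_duration_s`.
#' @export
extract_epochs <- function(rec, events, pre_s = 2, post_s = 12,
                           use_keep = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"), pre_s >= 0, post_s > 0)
  events <- as.data.frame(events)
  stopifnot(all(c("onset_s", "hand") %in% names(events)))
  if (is.null(events$keep)) events$keep <- TRUE
  if (is.null(events$unclench_s)) events$unclench_s <- events$onset_s + 4.5
  if (is.null(events$cue_duration_s)) events$cue_duration_s <- NA_real_
  fs <- rec$sampling_rate
  N <- nrow(rec$samples)
  len <- round((pre_s + post_s) * fs)
  out <- list()
  for (i in seq_len(nrow(events))) {
    if (use_keep && !isTRUE(events$keep[i])) next
    start0 <- round(events$onset_s[i] * fs) - round(pre_s * fs) # 0-based
    if (start0 < 0 || start0 + len > N) {
      warning(sprintf("event %d (onset %.2f s) out of bounds; epoch skipped",
                      i, events$onset_s[i]))
      next
    }
    ep <- structure(
      list(samples = rec$samples[(start0 + 1):(start0 + len), , drop = FALSE],
           sampling_rate = fs, channel_labels = rec$channel_labels,
           t0_offset_s = pre_s, hand = events$hand[i], trial = i,
           onset_s = events$onset_s[i], unclench_s = events$unclench_s[i],
           cue_duration_s = events$cue_duration_s[i]),
      class = "task_epoch")
    out[[length(out) + 1L]] <- ep
  }
  out
}
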