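#' Filter specification for signal conditioning
#'
#' Band edges for the analysis band-pass plus the line-noise notch.
#' Filtering is zero-phase (forward-backward) using cascaded Butterworth
#' sections: a high-pass at `band[1]`, a low-pass at `band[2]` and a
#' band-stop of width `notch_width` centred on `notch`. Forward-backward
#' application doubles the attenuation and cancels the phase response.
#'
#' @param band c(lo, hi) pass band in Hz; `0 < lo < hi < sfreq/2`.
#' @param notch line-noise frequency in Hz (inside the band); `NA` to skip.
#' @param notch_width full width of the band-stop in Hz.
#' @param order Butterworth section order (per pass; effective order is
#'   doubled by the forward-backward application).
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(band = c(2, 200), notch = 60, notch_width = 4,
                        order = 4) {
  if (band[1] <= 0 || band[1] >= band[2])
    stop("need 0 < band[1] < band[2]")
  if (!is.na(notch) && (notch <= band[1] || notch >= band[2]))
    stop("notch frequency must lie inside the pass band")
  structure(list(band = band, notch = notch, notch_width = notch_width,
                 order = order), class = "filter_spec")
}

# Zero-phase application of one signal::filter object along columns.
filtfilt_cols <- function(flt, x) {
  apply(x, 2, function(col) signal::filtfilt(flt, col))
}

#' Band-pass and notch filter a multichannel signal
#'
#' @param x numeric vector, or matrix `time x channels`.
#' @param spec a [filter_spec()].
#' @param sfreq sampling rate in Hz.
#' @return filtered signal, same shape as `x`.
#' @export
bandpass_notch <- function(x, spec = filter_spec(), sfreq) {
  if (spec$band[2] >= sfreq / 2)
    stop("upper band edge must be below the Nyquist frequency (",
         sfreq / 2, " Hz)")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  if (any(!is.finite(x))) stop("input contains non-finite samples")
  nyq <- sfreq / 2
  hp <- signal::butter(spec$order, spec$band[1] / nyq, type = "high")
  lp <- signal::butter(spec$order, spec$band[2] / nyq, type = "low")
  x <- filtfilt_cols(lp, filtfilt_cols(hp, x))
  if (!is.na(spec$notch)) {
    bs <- signal::butter(2, (spec$notch + c(-0.5, 0.5) * spec$notch_width) / nyq,
                         type = "stop")
    x <- filtfilt_cols(bs, x)
  }
  if (vec) x <- as.numeric(x)
  x
}

#' Re-reference epochs to the whole-scalp average
#'
#' Subtracts, at every trial and timepoint, the mean over channels, so
#' the channel mean is zero everywhere afterwards. Idempotent.
#'
#' @param epochs an [epoch_set()] with at least two channels.
#' @return re-referenced `epoch_set`.
#' @export
rereference_average <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (dim(epochs$data)[2] < 2)
    stop("average re-referencing needs at least 2 channels")
  mu <- apply(epochs$data, c(1, 3), mean)          # trials x time
  d <- dim(epochs$data)
  epochs$data <- epochs$data - aperm(array(mu, c(d[1], d[3], d[2])), c(1, 3, 2))
  epochs
}

#' Epoch a continuous recording and baseline-correct
#'
#' Cuts `span` ms around each stimulus onset out of a continuous
#' `time x channels` recording and subtracts, per epoch and channel, the
#' mean over `baseline` (a pre-onset window, in ms). Onsets whose epoch
#' would extend beyond the recording are dropped and counted.
#'
#' @param x continuous signal, matrix `time x channels`.
#' @param onsets stimulus-onset sample indices (1-based).
#' @param span c(pre, post) epoch limits in ms around onset.
#' @param sfreq sampling rate in Hz.
#' @param baseline c(lo, hi) baseline window in ms (`NULL` to skip
#'   baseline correction, as in the theta-power path).
#' @param metadata optional data.frame, one row per onset.
#' @return an [epoch_set()]; the number of dropped epochs is in
#'   `attr(, "n_dropped")`.
#' @export
epoch_and_baseline <- function(x, onsets, span, sfreq, baseline = c(-100, 0),
                               metadata = NULL) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  dt <- 1000 / sfreq
  rel <- seq(span[1], span[2] - dt / 2, by = dt)
  offs <- round(rel / dt)
  keep <- onsets + min(offs) >= 1 & onsets + max(offs) <= nrow(x)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " epoch(s) extended beyond the recording and were dropped")
  onsets <- onsets[keep]
  if (!is.null(metadata)) metadata <- metadata[keep, , drop = FALSE]
  if (!length(onsets)) stop("no epoch fits inside the recording")
  arr <- array(NA_real_, c(length(onsets), ncol(x), length(rel)))
  for (i in seq_along(onsets))
    arr[i, , ] <- t(x[onsets[i] + offs, , drop = FALSE])
  if (!is.null(baseline)) {
    bidx <- which(rel >= baseline[1] & rel <= baseline[2])
    if (!length(bidx)) stop("baseline window contains no samples")
    bmean <- apply(arr[, , bidx, drop = FALSE], c(1, 2), mean)
    arr <- arr - array(bmean, dim(arr))
  }
  out <- epoch_set(arr, rel, sfreq, metadata = metadata)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Theta-band Hilbert power of epoched data
#'
#' Per trial and channel: zero-phase Butterworth band-pass to the theta
#' band, then the analytic-signal envelope via the Hilbert transform.
#' Returns squared magnitude (power) by default, or the magnitude
#' itself. No baseline correction is applied on this path.
#'
#' @param epochs an [epoch_set()] of voltages.
#' @param band c(lo, hi) in Hz; default theta, 4-8 Hz inclusive.
#' @param output `"power"` (squared envelope) or `"magnitude"`.
#' @param order Butterworth order of the band-pass.
#' @return an `epoch_set` of non-negative band-power values.
#' @export
theta_power <- function(epochs, band = c(4, 8), output = c("power", "magnitude"),
                        order = 4) {
  stopifnot(inherits(epochs, "epoch_set"))
  output <- match.arg(output)
  d <- dim(epochs$data)
  # forward-backward IIR filtering needs samples to spare beyond the
  # filter's settling span
  if (d[3] < 12 * order)
    stop("epochs too short for the theta band-pass (need >= ", 12 * order,
         " samples)")
  nyq <- epochs$sfreq / 2
  if (band[2] >= nyq) stop("theta band must lie below Nyquist")
  flt <- signal::butter(order, band / nyq, type = "pass")
  out <- epochs$data
  for (i in seq_len(d[1])) {
    m <- array(epochs$data[i, , , drop = FALSE], c(d[2], d[3]))  # ch x time
    filt <- filtfilt_cols(flt, t(m))
    env <- apply(matrix(filt, d[3], d[2]), 2,
                 function(col) Mod(analytic_signal(col)))
    out[i, , ] <- t(matrix(env, d[3], d[2]))
  }
  epochs$data <- out
  epochs
}
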