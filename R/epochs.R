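#' Construct an epoch set
#'
#' The central container of the package: a 3-d array of epoched EEG
#' (trials x channels x time) together with its time axis, sampling rate,
#' channel labels and one row of per-trial metadata per epoch.
#'
#' @param data numeric array, `trials x channels x time`. Voltage (uV) or
#'   band power, depending on the processing stage.
#' @param times numeric vector of sample times in ms relative to stimulus
#'   onset; length must equal `dim(data)[3]`.
#' @param sfreq sampling rate in Hz.
#' @param channels character vector of channel labels; length
#'   `dim(data)[2]`.
#' @param metadata data.frame with one row per trial. Typical columns:
#'   `subject`, `condition` (Session 1), `item`, `round`, `trial_type`
#'   (Session 2).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, sfreq, channels = NULL, metadata = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (trials x channels x time)")
  d <- dim(data)
  if (length(times) != d[3])
    stop("length(times) must equal the time dimension of `data`")
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing")
  if (is.null(channels)) channels <- sprintf("Ch%02d", seq_len(d[2]))
  if (length(channels) != d[2])
    stop("length(channels) must equal the channel dimension of `data`")
  if (is.null(metadata)) metadata <- data.frame(trial = seq_len(d[1]))
  if (!is.data.frame(metadata) || nrow(metadata) != d[1])
    stop("`metadata` must be a data.frame with one row per trial")
  structure(
    list(data = data, times = as.numeric(times), sfreq = sfreq,
         channels = channels, metadata = metadata),
    class = "epoch_set")
}

#' @exportS3Method base::print
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples @ %g Hz, %.0f..%.0f ms\n",
    d[1], d[2], d[3], x$sfreq, min(x$times), max(x$times)))
  cat("metadata columns:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Number of trials in an epoch set
#' @param epochs an [epoch_set()].
#' @return integer trial count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' Subset an epoch set by trial
#' @param epochs an [epoch_set()].
#' @param idx integer or logical trial index.
#' @return an `epoch_set` with the selected trials.
#' @export
subset_trials <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$times, epochs$sfreq,
            epochs$channels, epochs$metadata[idx, , drop = FALSE])
}
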