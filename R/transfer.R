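#' Train full-data classifiers at selected training timepoints
#'
#' One ridge logistic model per training timepoint, fit on *all*
#' Session 1 trials (no held-out split) — these are the models that get
#' transferred to Session 2.
#'
#' @param wf Session 1 [sliding_window_features()].
#' @param labels per-trial class labels; the positive
#'   (high-competition) class is the one sorting last (e.g. `"high"` vs
#'   `"low"` with `positive = "high"` explicitly).
#' @param train_index indices into `wf$start_times` to train at
#'   (typically the selected localizer window); default all.
#' @param positive label of the high-competition class; classifier
#'   output is the probability of this class.
#' @inheritParams crossval_decode
#' @return list of class `transfer_models`: per-timepoint models
#'   (`weights`, `intercept`), `train_times`, `positive`.
#' @export
train_full_models <- function(wf, labels, train_index = NULL, positive = "high",
                              C = 1, standardize = FALSE) {
  if (is.null(train_index)) train_index <- seq_along(wf$start_times)
  if (!all(positive %in% labels)) stop("positive class not present in labels")
  y <- as.integer(labels == positive)
  if (length(unique(y)) != 2L) stop("both classes must be present")
  models <- lapply(train_index, function(k)
    fit_ridge_logistic(features_at(wf, k), y, C = C, standardize = standardize))
  structure(list(models = models, train_times = wf$start_times[train_index],
                 positive = positive, n_channels = dim(wf$features)[2]),
            class = "transfer_models")
}

#' Apply transferred classifiers across Session 2 timepoints
#'
#' Evaluates every trained Session 1 model at every Session 2 window
#' start time, yielding the competition probability — the logistic
#' output, read as P(high-competition state) — for each trial at each
#' (training time, testing time) grid square. Probabilities are clipped
#' to `[eps, 1 - eps]` for downstream arithmetic stability.
#'
#' @param models a [train_full_models()] result.
#' @param wf Session 2 [sliding_window_features()] (same channel set and
#'   windowing scheme as in training).
#' @param test_min_ms earliest test window start to keep (default 0:
#'   post-onset timepoints only).
#' @param eps clipping bound for probabilities.
#' @return list of class `competition_grid`: `values` (array
#'   `trials x train_times x test_times`), `train_times`, `test_times`,
#'   `metadata` (per-trial rows from `wf`).
#' @export
apply_grid <- function(models, wf, test_min_ms = 0, eps = 1e-6) {
  stopifnot(inherits(models, "transfer_models"))
  if (dim(wf$features)[2] != models$n_channels)
    stop("channel dimension mismatch between models and features")
  test_idx <- which(wf$start_times >= test_min_ms)
  if (!length(test_idx)) stop("no test timepoints at or after test_min_ms")
  n_tr <- dim(wf$features)[1]
  vals <- array(NA_real_,
                c(n_tr, length(models$train_times), length(test_idx)))
  for (j in seq_along(test_idx)) {
    xj <- features_at(wf, test_idx[j])
    for (i in seq_along(models$models))
      vals[, i, j] <- predict_logistic(models$models[[i]], xj)
  }
  vals <- clip(vals, eps, 1 - eps)
  structure(list(values = vals, train_times = models$train_times,
                 test_times = wf$start_times[test_idx],
                 metadata = wf$metadata),
            class = "competition_grid")
}

#' @exportS3Method base::print
print.competition_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<competition_grid> %d trials, %d train x %d test timepoints\n",
              d[1], d[2], d[3]))
  invisible(x)
}
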