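#' Sliding-window channel-mean features
#'
#' For each start time on a `step_ms` grid, averages every channel over
#' the half-open window `[t, t + window_ms)` (membership decided on the
#' sample-time grid), producing one `n_channels`-dimensional feature
#' vector per trial per start time. Start times whose window does not
#' fit fully inside the epoch are excluded and counted.
#'
#' @param epochs an [epoch_set()].
#' @param window_ms window length in ms.
#' @param step_ms spacing of window start times in ms.
#' @return list of class `window_features`: `features` (array
#'   `trials x channels x n_starts`), `start_times` (ms), `metadata`
#'   (the epochs' per-trial metadata), plus the window parameters.
#' @export
sliding_window_features <- function(epochs, window_ms = 50, step_ms = 20) {
  stopifnot(inherits(epochs, "epoch_set"))
  tms <- epochs$times
  dt <- 1000 / epochs$sfreq
  candidates <- seq(tms[1], tms[length(tms)], by = step_ms)
  # the window [t, t+w) must lie inside the sampled span [t1, tN + dt)
  fits <- candidates + window_ms <= tms[length(tms)] + dt + 1e-9
  n_excluded <- sum(!fits)
  if (n_excluded > 0)
    message(n_excluded, " window start(s) extended past the epoch and were excluded")
  starts <- candidates[fits]
  if (!length(starts)) stop("no sliding window fits inside the epoch")
  d <- dim(epochs$data)
  feats <- array(NA_real_, c(d[1], d[2], length(starts)))
  for (k in seq_along(starts)) {
    idx <- which(tms >= starts[k] - 1e-9 & tms < starts[k] + window_ms - 1e-9)
    feats[, , k] <- rowMeans(epochs$data[, , idx, drop = FALSE], dims = 2)
  }
  structure(list(features = feats, start_times = starts,
                 window_ms = window_ms, step_ms = step_ms,
                 metadata = epochs$metadata, channels = epochs$channels),
            class = "window_features")
}

# feature matrix (trials x channels) at one start time
features_at <- function(wf, k) {
  d <- dim(wf$features)
  matrix(wf$features[, , k], d[1], d[2])
}

#' Cross-validated decoding accuracy at one timepoint
#'
#' Stratified k-fold cross-validation of an L2-penalized (ridge)
#' logistic regression on a trials x channels feature matrix; returns
#' the mean held-out accuracy.
#'
#' @param x feature matrix, trials x channels.
#' @param y binary labels (two classes, any coding).
#' @param n_folds number of folds.
#' @param seed seed for the stratified fold assignment.
#' @param C inverse regularization strength of the ridge penalty.
#' @param standardize standardize features before fitting (off by
#'   default: window means share a common voltage scale).
#' @return mean held-out accuracy in `[0, 1]`.
#' @export
crossval_decode <- function(x, y, n_folds = 5, seed = 1, C = 1,
                            standardize = FALSE) {
  y01 <- as.integer(factor(y)) - 1L
  if (length(unique(y01)) != 2L) stop("need exactly two classes")
  fold <- stratified_folds(y01, n_folds, seed)
  correct <- logical(length(y01))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (length(unique(y01[tr])) != 2L)
      stop("a training fold is missing a class; re-stratify")
    model <- fit_ridge_logistic(x[tr, , drop = FALSE], y01[tr], C = C,
                                standardize = standardize)
    p <- predict_logistic(model, x[!tr, , drop = FALSE])
    correct[!tr] <- (p > 0.5) == (y01[!tr] == 1L)
  }
  mean(correct)
}

#' Within-subject permutation test of decoding accuracy
#'
#' Re-runs the full cross-validation under label permutations and
#' returns the add-one permutation p value
#' `p = (1 + #\{perm accuracy >= observed\}) / (n_perm + 1)`, which is
#' always in `(0, 1]`.
#'
#' @inheritParams crossval_decode
#' @param n_perm number of label permutations.
#' @return list: `p`, `observed` accuracy, `perm_acc` vector.
#' @export
within_subject_permutation_p <- function(x, y, n_folds = 5, n_perm = 100,
                                         seed = 1, C = 1, standardize = FALSE) {
  observed <- crossval_decode(x, y, n_folds, seed = seed, C = C,
                              standardize = standardize)
  perm_acc <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    ys <- withr::with_seed(child_seed(seed, 300L + b), sample(y))
    perm_acc[b] <- crossval_decode(x, ys, n_folds,
                                   seed = child_seed(seed, 600L + b),
                                   C = C, standardize = standardize)
  }
  list(p = (1 + sum(perm_acc >= observed)) / (n_perm + 1),
       observed = observed, perm_acc = perm_acc)
}

#' Sliding-window decoding curve for one subject
#'
#' Applies [crossval_decode()] (and optionally the within-subject
#' permutation test) at every window start time.
#'
#' @param wf a [sliding_window_features()] object for one subject.
#' @param labels per-trial class labels.
#' @param n_perm permutations per timepoint (0 skips the test).
#' @inheritParams crossval_decode
#' @return data.frame: `start_time`, `accuracy`, and `p` when
#'   `n_perm > 0`.
#' @export
decode_sliding <- function(wf, labels, n_folds = 5, n_perm = 0, seed = 1,
                           C = 1, standardize = FALSE) {
  acc <- p <- numeric(length(wf$start_times))
  for (k in seq_along(wf$start_times)) {
    xk <- features_at(wf, k)
    sk <- child_seed(seed, k)
    if (n_perm > 0) {
      r <- within_subject_permutation_p(xk, labels, n_folds, n_perm, seed = sk,
                                        C = C, standardize = standardize)
      acc[k] <- r$observed; p[k] <- r$p
    } else {
      acc[k] <- crossval_decode(xk, labels, n_folds, seed = sk, C = C,
                                standardize = standardize)
    }
  }
  out <- data.frame(start_time = wf$start_times, accuracy = acc)
  if (n_perm > 0) out$p <- p
  out
}

#' Group-level significance from per-subject permutation p values
#'
#' Combines within-subject permutation p values across subjects by the
#' inverse-normal (Stouffer-style random effects) route: each p becomes
#' `z = qnorm(1 - p)` (clipped away from 0 and 1 so z stays finite), and
#' a one-sample, one-sided t-test of the z values against zero gives the
#' group p per timepoint. The significance mask applies a Bonferroni
#' threshold of `alpha / T` over the `T` timepoints.
#'
#' @param p_matrix subjects x timepoints matrix of within-subject p
#'   values.
#' @param alpha initial group significance level before the Bonferroni
#'   division (default 0.001).
#' @param p_clip p values are clipped to `[p_clip, 1 - p_clip]` before
#'   the transform; default `1/101`, the resolution of a
#'   100-permutation test.
#' @return list: `z` matrix, `group_p` per timepoint, `threshold`
#'   (`alpha / T`), logical `mask`.
#' @export
group_significance <- function(p_matrix, alpha = 0.001, p_clip = 1 / 101) {
  p_matrix <- as.matrix(p_matrix)
  if (nrow(p_matrix) < 3)
    stop("group t-test needs at least 3 subjects")
  z <- stats::qnorm(1 - clip(p_matrix, p_clip, 1 - p_clip))
  group_p <- apply(z, 2, function(zt) {
    if (stats::sd(zt) == 0) return(if (mean(zt) > 0) 0 else 1)
    stats::t.test(zt, mu = 0, alternative = "greater")$p.value
  })
  threshold <- alpha / ncol(p_matrix)
  list(z = z, group_p = group_p, threshold = threshold,
       mask = group_p < threshold)
}

#' Select the discriminative time window
#'
#' Returns the window of start times that are both group-significant and
#' more than `sd_mult` across-subject standard deviations above chance,
#' after bridging internal dips shorter than `bridge_ms`. When several
#' disjoint runs survive, the longest (earliest on ties) is returned.
#'
#' @param start_times window start times in ms.
#' @param group_acc group-mean accuracy per start time.
#' @param group_sd across-subject SD of accuracy per start time.
#' @param mask logical group-significance mask (from
#'   [group_significance()]).
#' @param chance chance accuracy (0.5 for balanced two-class decoding).
#' @param sd_mult how many SDs above chance accuracy must be.
#' @param bridge_ms dips shorter than this are absorbed into the
#'   surrounding run rather than splitting it.
#' @return list: `t_start`, `t_end` (ms), `index` of selected start
#'   times; or `NULL` fields when no timepoint qualifies.
#' @export
select_time_window <- function(start_times, group_acc, group_sd, mask,
                               chance = 0.5, sd_mult = 1.0, bridge_ms = 120) {
  crit <- mask & (group_acc > chance + sd_mult * group_sd)
  if (!any(crit))
    return(list(t_start = NULL, t_end = NULL, index = integer(0)))
  step <- if (length(start_times) > 1) diff(start_times)[1] else bridge_ms
  r <- rle(crit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  # bridge FALSE gaps strictly inside the masked region that are shorter
  # than bridge_ms
  for (j in seq_along(r$values)) {
    if (!r$values[j] && j > 1 && j < length(r$values) &&
        r$lengths[j] * step <= bridge_ms)
      crit[starts[j]:ends[j]] <- TRUE
  }
  r <- rle(crit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]   # which.max takes the first tie
  idx <- starts[best]:ends[best]
  list(t_start = start_times[idx[1]], t_end = start_times[idx[length(idx)]],
       index = idx)
}
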