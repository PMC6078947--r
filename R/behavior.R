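#' Encode per-item response configurations
#'
#' Collapses the per-round correctness of each item into a binary
#' configuration string whose i-th character is 1 when the item was
#' answered correctly in round i (e.g. correct in all but round 1 is
#' `"0111"`). The encoding is a bijection between correctness sequences
#' and configurations.
#'
#' @param behavior behavioral table (`subject`, `item`, `round`,
#'   `correct`, `recalled_s3`); every item must cover every round.
#' @return data.frame: `subject`, `item`, `configuration`, `bits`
#'   (matrix column per round), `recalled_s3`.
#' @export
encode_configurations <- function(behavior) {
  n_rounds <- max(behavior$round)
  b <- behavior[order(behavior$subject, behavior$item, behavior$round), ]
  key <- paste(b$subject, b$item)
  counts <- table(key)
  if (any(counts != n_rounds))
    stop("every item needs a correctness value for every round")
  first <- !duplicated(key)
  # rows are grouped by item with rounds in order; reshape one item per row
  bits <- t(matrix(b$correct, nrow = n_rounds))
  out <- data.frame(subject = b$subject[first], item = b$item[first],
                    configuration = apply(bits, 1, paste, collapse = ""),
                    recalled_s3 = b$recalled_s3[first])
  out$bits <- bits
  out
}

#' Predict delayed recall from response configurations
#'
#' Cross-validated accuracy of an L2-penalized logistic regression that
#' predicts the delayed-recall label from the per-round correctness
#' bits, items pooled over subjects (optionally grouped CV holding
#' subjects out).
#'
#' @param configs an [encode_configurations()] result (or a 0/1 matrix
#'   of per-round bits).
#' @param recalled_s3 binary outcome per item (taken from `configs` when
#'   omitted).
#' @param n_folds cross-validation folds.
#' @param seed fold-assignment seed.
#' @param C inverse ridge regularization strength.
#' @param group_by_subject hold out whole subjects instead of stratified
#'   item folds.
#' @return mean held-out accuracy.
#' @export
predict_s3_from_configurations <- function(configs, recalled_s3 = NULL,
                                           n_folds = 5, seed = 1, C = 1,
                                           group_by_subject = FALSE) {
  if (is.data.frame(configs)) {
    x <- configs$bits
    if (is.null(recalled_s3)) recalled_s3 <- configs$recalled_s3
    subject <- configs$subject
  } else {
    x <- as.matrix(configs)
    subject <- NULL
  }
  y <- as.integer(recalled_s3)
  if (length(unique(y)) != 2L) stop("need both outcome classes")
  if (group_by_subject) {
    if (is.null(subject)) stop("grouped CV needs subject ids")
    us <- sort(unique(subject))
    sf <- stratified_folds(rep(1L, length(us)), min(n_folds, length(us)), seed)
    fold <- sf[match(subject, us)]
    n_folds <- max(fold)
  } else {
    fold <- stratified_folds(y, n_folds, seed)
  }
  correct <- logical(length(y))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) != 2L) stop("a training fold is missing a class")
    model <- fit_ridge_logistic(x[tr, , drop = FALSE], y[tr], C = C)
    p <- predict_logistic(model, x[!tr, , drop = FALSE])
    correct[!tr] <- (p > 0.5) == (y[!tr] == 1L)
  }
  mean(correct)
}

#' Permutation test of the behavioral prediction
#'
#' Shuffles the delayed-recall labels before cross-validation, `n_perm`
#' times, and returns the add-one permutation p value of the observed
#' accuracy.
#'
#' @inheritParams predict_s3_from_configurations
#' @param n_perm number of permutations.
#' @return list: `p`, `observed`, `perm_acc`.
#' @export
behavior_permutation_test <- function(configs, recalled_s3 = NULL,
                                      n_perm = 1000, n_folds = 5, seed = 1,
                                      C = 1) {
  if (is.data.frame(configs) && is.null(recalled_s3))
    recalled_s3 <- configs$recalled_s3
  x <- if (is.data.frame(configs)) configs$bits else as.matrix(configs)
  y <- as.integer(recalled_s3)
  observed <- predict_s3_from_configurations(x, y, n_folds, seed = seed, C = C)
  perm_acc <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    ys <- withr::with_seed(child_seed(seed, 7000L + b), sample(y))
    perm_acc[b] <- predict_s3_from_configurations(
      x, ys, n_folds, seed = child_seed(seed, 8000L + b), C = C)
  }
  list(p = (1 + sum(perm_acc >= observed)) / (n_perm + 1),
       observed = observed, perm_acc = perm_acc)
}

#' Per-round recall summary split by delayed-recall outcome
#'
#' Mean-of-subject-means recall accuracy per round (each subject's mean
#' is computed first, then averaged — not the pooled-trial mean), with
#' the standard error over subject means, overall and split by the
#' delayed-recall outcome.
#'
#' @param behavior behavioral table.
#' @return data.frame: `round`, `group` (`all` / `remembered` /
#'   `forgotten`), `mean_accuracy`, `sem`, `n_subjects`. `sem` is `NA`
#'   with a single contributing subject.
#' @export
summarize_rounds <- function(behavior) {
  groups <- list(all = rep(TRUE, nrow(behavior)),
                 remembered = behavior$recalled_s3 == 1,
                 forgotten = behavior$recalled_s3 == 0)
  out <- list()
  for (gname in names(groups)) {
    b <- behavior[groups[[gname]], ]
    if (!nrow(b)) next
    for (r in sort(unique(behavior$round))) {
      br <- b[b$round == r, ]
      sm <- tapply(br$correct, br$subject, mean)
      sm <- sm[!is.na(sm)]
      out[[paste(gname, r)]] <- data.frame(
        round = r, group = gname, mean_accuracy = mean(sm),
        sem = if (length(sm) > 1) stats::sd(sm) / sqrt(length(sm)) else NA_real_,
        n_subjects = length(sm))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
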