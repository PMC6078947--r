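# Internal helpers shared across modules.

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a stream-specific child seed from a base seed. Double arithmetic
# (exact below 2^53) keeps the result a valid 32-bit integer seed.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(k)) %% 2147483647)
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each observation to one of `k` folds so that class proportions
#' are preserved as closely as possible. Deterministic given `seed`.
#'
#' @param y class label vector (two or more classes).
#' @param k number of folds.
#' @param seed integer seed for the shuffle.
#' @return integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(y, k = 5, seed = 1) {
  if (k < 2) stop("need at least 2 folds")
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(sample(seq_len(k)), length(idx))
    }
  })
  # every training set (all folds but one) must contain every class
  tab <- table(factor(fold, levels = seq_len(k)), y)
  if (any(colSums(tab > 0) < 2) && any(table(y) >= 2))
    stop("a class fell entirely into one fold; use fewer folds or more trials")
  fold
}

# L2-penalized (ridge) logistic regression via glmnet at a single lambda.
# `C` follows the usual inverse-regularization convention: the glmnet
# objective (1/n) * deviance/2 + lambda/2 * ||w||^2 matches penalty 1/C per
# observation when lambda = 1 / (n * C).
fit_ridge_logistic <- function(x, y, C = 1, standardize = FALSE) {
  y <- as.integer(y)
  if (length(unique(y)) != 2L) stop("need exactly two classes to fit")
  lam <- 1 / (nrow(x) * C)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lam,
                        standardize = standardize, thresh = 1e-9)
  w <- as.numeric(fit$beta[, 1])
  list(weights = w, intercept = as.numeric(fit$a0[1]), C = C)
}

predict_logistic <- function(model, x) {
  as.numeric(stats::plogis(x %*% model$weights + model$intercept))
}

# Analytic signal by the frequency-domain construction: zero the negative
# frequencies, double the positive ones, keep DC (and Nyquist for even n).
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}
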