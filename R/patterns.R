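#' Representational dissimilarity matrix over classifier weight vectors
#'
#' Pairwise cosine distance `1 - cos(w_i, w_j)` between the weight
#' vectors learned at each timepoint. Entries lie in `[0, 2]` with a
#' zero diagonal; the matrix is invariant to positive rescaling of any
#' weight vector.
#'
#' @param weights matrix `timepoints x channels` of weight vectors, or a
#'   list of per-timepoint models with a `weights` field.
#' @return symmetric distance matrix, `timepoints x timepoints`.
#' @export
weight_rdm <- function(weights) {
  if (is.list(weights) && !is.data.frame(weights))
    weights <- do.call(rbind, lapply(weights, function(m) m$weights))
  weights <- as.matrix(weights)
  nrm <- sqrt(rowSums(weights^2))
  if (any(nrm == 0)) stop("zero-norm weight vector: cosine distance undefined")
  wn <- weights / nrm
  d <- 1 - tcrossprod(wn)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  clip(d, 0, 2)
}

#' Haufe transform: classifier weights to activation pattern
#'
#' Converts a linear decoder's weight vector into an interpretable
#' activation pattern by multiplying with the empirical channel
#' covariance of the training features at that timepoint
#' (`a = Sigma_X w`, the binary-classifier case of the weight-to-pattern
#' transform). The raw pattern is returned; normalization happens when
#' averaging across subjects (see [average_patterns()]).
#'
#' @param weights per-channel weight vector (or a model with a
#'   `weights` field).
#' @param x training feature matrix `trials x channels` at the same
#'   timepoint.
#' @param shrinkage optional shrinkage intensity in `[0, 1]` toward the
#'   scaled identity (0 = plain maximum-likelihood covariance).
#' @return numeric activation pattern of length `n_channels`.
#' @export
haufe_pattern <- function(weights, x, shrinkage = 0) {
  if (is.list(weights)) weights <- weights$weights
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("covariance not estimable from a single trial")
  if (length(weights) != ncol(x))
    stop("weight length must match the number of channels")
  xc <- sweep(x, 2, colMeans(x))
  sigma <- crossprod(xc) / nrow(x)          # ML covariance
  if (shrinkage > 0) {
    target <- diag(mean(diag(sigma)), ncol(sigma))
    sigma <- (1 - shrinkage) * sigma + shrinkage * target
  }
  as.numeric(sigma %*% weights)
}

#' Average activation patterns over subjects and timepoints
#'
#' Each pattern is normalized to unit norm first (so high-variance
#' subjects do not dominate), then patterns are averaged element-wise
#' over the selection.
#'
#' @param patterns list of per-channel patterns (or a matrix with one
#'   pattern per row), e.g. all (subject, timepoint) patterns whose
#'   timepoint falls in a window of interest.
#' @param normalize normalize each pattern to unit norm before
#'   averaging.
#' @return averaged pattern, length `n_channels`.
#' @export
average_patterns <- function(patterns, normalize = TRUE) {
  if (is.list(patterns)) patterns <- do.call(rbind, patterns)
  patterns <- as.matrix(patterns)
  if (!nrow(patterns)) stop("empty pattern selection")
  if (normalize) {
    nrm <- sqrt(rowSums(patterns^2))
    if (any(nrm == 0)) stop("zero-norm pattern cannot be normalized")
    patterns <- patterns / nrm
  }
  colMeans(patterns)
}
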