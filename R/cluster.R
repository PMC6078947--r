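# Vectorized two-sample t statistics for every column of X (items x
# squares), comparing rows where g is TRUE vs FALSE. Student (pooled
# variance) by default, Welch optionally.
t_columns <- function(X, g, var_equal = TRUE) {
  n1 <- sum(g); n2 <- sum(!g)
  if (n1 < 2 || n2 < 2) stop("each outcome class needs at least 2 items")
  x1 <- X[g, , drop = FALSE]; x2 <- X[!g, , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  ss1 <- colSums(x1^2) - n1 * m1^2
  ss2 <- colSums(x2^2) - n2 * m2^2
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- (ss1 + ss2) / df
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(df, length(t))
  } else {
    v1 <- ss1 / (n1 - 1) / n1; v2 <- ss2 / (n2 - 1) / n2
    t <- (m1 - m2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  list(t = t, df = df)
}

drop_matrix <- function(table) {
  d <- dim(table$drops)
  matrix(table$drops, d[1], d[2] * d[3])
}

#' Grid-wise pooled t-test of competition drops
#'
#' At every (train time, test time) square, a two-sample t-test of the
#' drop values for subsequently-remembered vs subsequently-forgotten
#' items, pooled over subjects (a fixed-effects test; family-wise
#' correction happens downstream). Both one-tailed p values are
#' returned: the right tail (drop larger for remembered — the
#' directional hypothesis) and the left tail.
#'
#' @param table a [competition_drop()] table.
#' @param var_equal pooled-variance Student t (default) or Welch.
#' @return list: `t`, `p_right`, `p_left` (matrices
#'   `train_times x test_times`), `df`, class counts.
#' @export
grid_ttest <- function(table, var_equal = TRUE) {
  stopifnot(inherits(table, "drop_table"))
  g <- table$items$recalled_s3 == 1
  r <- t_columns(drop_matrix(table), g, var_equal)
  d <- dim(table$drops)
  shape <- function(v) matrix(v, d[2], d[3],
                              dimnames = list(table$train_times,
                                              table$test_times))
  list(t = shape(r$t),
       p_right = shape(stats::pt(r$t, r$df, lower.tail = FALSE)),
       p_left = shape(stats::pt(r$t, r$df)),
       df = r$df[1], n_remembered = sum(g), n_forgotten = sum(!g))
}

#' Kolmogorov-Smirnov normality diagnostic per outcome class
#'
#' Tests each class's drop values against a normal distribution with
#' the class's estimated mean and SD. A diagnostic, not a gate: the
#' t-test is run regardless.
#'
#' @param drops_by_class named list of numeric vectors (e.g.
#'   `list(remembered = ..., forgotten = ...)`).
#' @param min_n classes with fewer values are skipped with a warning.
#' @return data.frame: `class`, `n`, `statistic`, `p` (NA when skipped).
#' @export
ks_normality_check <- function(drops_by_class, min_n = 10) {
  out <- lapply(names(drops_by_class), function(nm) {
    x <- drops_by_class[[nm]]
    if (length(x) < min_n) {
      warning("class '", nm, "' has fewer than ", min_n,
              " values; KS diagnostic skipped")
      return(data.frame(class = nm, n = length(x), statistic = NA_real_,
                        p = NA_real_))
    }
    k <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    data.frame(class = nm, n = length(x), statistic = unname(k$statistic),
               p = k$p.value)
  })
  do.call(rbind, out)
}

#' Connected clusters of sub-threshold grid squares
#'
#' Connected components of `p < threshold` squares under 4-connectivity
#' (immediately adjacent timepoints; diagonal adjacency does not
#' connect). Cluster size is the number of member squares.
#'
#' @param p_grid matrix of p values (train x test), or a logical mask
#'   (then `threshold` is ignored).
#' @param threshold inclusion threshold on p.
#' @return list: `labels` (integer matrix, 0 = background), `sizes`
#'   (vector, one per cluster, in label order), `clusters` (list of
#'   member-square index matrices, columns `row`/`col`).
#' @export
find_clusters <- function(p_grid, threshold = 0.10) {
  mask <- if (is.logical(p_grid)) p_grid else p_grid < threshold
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  lab <- 0L
  stack <- integer(nr * nc)
  for (start in which(mask & labels == 0L)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    top <- 1L; stack[1] <- start
    labels[start] <- lab
    while (top > 0L) {
      v <- stack[top]; top <- top - 1L
      i <- (v - 1L) %% nr + 1L
      j <- (v - 1L) %/% nr + 1L
      for (nb in c(if (i > 1L) v - 1L, if (i < nr) v + 1L,
                   if (j > 1L) v - nr, if (j < nc) v + nr)) {
        if (mask[nb] && labels[nb] == 0L) {
          labels[nb] <- lab
          top <- top + 1L; stack[top] <- nb
        }
      }
    }
  }
  sizes <- if (lab > 0L) tabulate(labels[labels > 0L], lab) else integer(0)
  clusters <- lapply(seq_len(lab), function(l) {
    which(labels == l, arr.ind = TRUE)
  })
  list(labels = labels, sizes = sizes, clusters = clusters)
}

# Shuffle the remembered/forgotten assignment over pooled items
# (optionally preserving per-subject class counts).
permute_labels <- function(g, subject, stratify) {
  if (!stratify) return(sample(g))
  out <- g
  for (s in unique(subject)) {
    idx <- which(subject == s)
    out[idx] <- sample(g[idx])
  }
  out
}

#' Cluster-based permutation test of the drop-memory association
#'
#' Two-stage family-wise correction over the (train, test) grid: the
#' right-tailed p grid is thresholded (`p < threshold`), clusters of
#' contiguous squares are formed under 4-connectivity, and each observed
#' cluster's size is compared with the null distribution of *maximum*
#' cluster sizes obtained by permuting the assignment of pooled items to
#' the remembered/forgotten classes. The family-wise p uses the add-one
#' estimator; clusters with family-wise p below `alpha` are significant.
#' The null uses the same right-tailed mask as the observed test (the
#' hypothesis is directional); the left-tailed map is reported
#' descriptively.
#'
#' @param table a [competition_drop()] table.
#' @param n_perm number of label permutations.
#' @param threshold cluster-forming p threshold.
#' @param alpha family-wise significance level.
#' @param seed permutation seed.
#' @param var_equal see [grid_ttest()].
#' @param stratify_by_subject shuffle labels within subject instead of
#'   over the pooled item set (sensitivity variant; default pooled).
#' @return list of class `cluster_result`: the [grid_ttest()] fields,
#'   `mask` (right-tailed), `mask_left`, `clusters` (data.frame: `label`,
#'   `size`, `fw_p`, `significant`), `labels` matrix, `null_max_sizes`,
#'   `threshold`, `alpha`.
#' @export
cluster_permutation <- function(table, n_perm = 1000, threshold = 0.10,
                                alpha = 0.05, seed = 1, var_equal = TRUE,
                                stratify_by_subject = FALSE) {
  stopifnot(inherits(table, "drop_table"))
  if (n_perm < 100)
    warning("fewer than 100 permutations gives an unstable null tail")
  tt <- grid_ttest(table, var_equal)
  mask <- tt$p_right < threshold
  cl <- find_clusters(mask)
  X <- drop_matrix(table)
  g <- table$items$recalled_s3 == 1
  subject <- table$items$subject
  null_max <- withr::with_seed(child_seed(seed, 11L), {
    vapply(seq_len(n_perm), function(b) {
      gp <- permute_labels(g, subject, stratify_by_subject)
      r <- t_columns(X, gp, var_equal)
      pm <- stats::pt(r$t, r$df, lower.tail = FALSE) < threshold
      sz <- find_clusters(matrix(pm, nrow(mask), ncol(mask)))$sizes
      if (length(sz)) max(sz) else 0L
    }, 0L)
  })
  fw_p <- vapply(cl$sizes, function(s) (1 + sum(null_max >= s)) / (n_perm + 1),
                 0)
  clusters <- data.frame(label = seq_along(cl$sizes), size = cl$sizes,
                         fw_p = fw_p, significant = fw_p < alpha)
  structure(c(tt, list(mask = mask, mask_left = tt$p_left < threshold,
                       clusters = clusters, labels = cl$labels,
                       cluster_squares = cl$clusters,
                       null_max_sizes = null_max,
                       threshold = threshold, alpha = alpha)),
            class = "cluster_result")
}

#' @exportS3Method base::print
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s) at p < %.2f threshold\n",
              nrow(x$clusters), x$threshold))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Significant-cluster membership matrix of a cluster result
#' @param result a [cluster_permutation()] result.
#' @return logical matrix (train x test), TRUE inside family-wise
#'   significant clusters.
#' @export
significant_squares <- function(result) {
  sig <- result$clusters$label[result$clusters$significant]
  matrix(result$labels %in% sig, nrow(result$labels), ncol(result$labels))
}

#' Subject bootstrap of cluster reliability
#'
#' Resamples subjects with replacement (duplicating their items), reruns
#' the full cluster permutation analysis per draw, and reports, per grid
#' square, the fraction of draws in which the square fell inside a
#' family-wise significant cluster. Draws whose resample contains a
#' single outcome class are skipped and removed from the denominator.
#'
#' @param table a [competition_drop()] table with at least two subjects.
#' @param n_boot number of bootstrap draws.
#' @param n_perm permutations per draw.
#' @param seed bootstrap seed.
#' @inheritParams cluster_permutation
#' @return list: `freq` (train x test inclusion-frequency matrix in
#'   `[0,1]`), `n_valid`, `n_skipped`.
#' @export
subject_bootstrap <- function(table, n_boot = 1000, n_perm = 200,
                              threshold = 0.10, alpha = 0.05, seed = 1,
                              var_equal = TRUE) {
  stopifnot(inherits(table, "drop_table"))
  subjects <- unique(table$items$subject)
  if (length(subjects) < 2) stop("subject bootstrap needs at least 2 subjects")
  d <- dim(table$drops)
  counts <- matrix(0, d[2], d[3])
  n_valid <- n_skipped <- 0L
  for (b in seq_len(n_boot)) {
    draw <- withr::with_seed(child_seed(seed, 5000L + b),
                             sample(subjects, replace = TRUE))
    idx <- unlist(lapply(draw, function(s) which(table$items$subject == s)))
    boot <- subset_drop_table(table, idx)
    if (length(unique(boot$items$recalled_s3)) < 2 ||
        min(table(boot$items$recalled_s3)) < 2) {
      n_skipped <- n_skipped + 1L
      next
    }
    res <- cluster_permutation(boot, n_perm = n_perm, threshold = threshold,
                               alpha = alpha, seed = child_seed(seed, b),
                               var_equal = var_equal)
    counts <- counts + significant_squares(res)
    n_valid <- n_valid + 1L
  }
  if (n_skipped > 0)
    message(n_skipped, " bootstrap draw(s) had a single outcome class and were skipped")
  if (n_valid == 0) stop("no valid bootstrap draw")
  list(freq = counts / n_valid, n_valid = n_valid, n_skipped = n_skipped)
}
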