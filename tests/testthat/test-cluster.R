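test_that("the pooled grid t-test matches a from-scratch formula and t.test", {
  # toy groups from the printed example
  a <- c(1, 2, 3); b <- c(0, 1, 2)
  drops <- array(c(a, b), c(6, 1, 1))
  tab <- toy_drop_table(drops, data.frame(subject = 1, item = 1:6,
                                          configuration = "0011",
                                          recalled_s3 = rep(c(1, 0), each = 3)))
  r <- grid_ttest(tab)
  # from-scratch pooled-variance formula
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 4
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(r$t[1, 1], t_manual)
  expect_equal(r$p_right[1, 1], pt(t_manual, 4, lower.tail = FALSE))
  # independent route: stats::t.test
  tt <- t.test(a, b, var.equal = TRUE, alternative = "greater")
  expect_equal(r$t[1, 1], unname(tt$statistic))
  expect_equal(r$p_right[1, 1], tt$p.value)
  expect_equal(r$p_left[1, 1], 1 - tt$p.value)
  # Welch variant agrees with t.test too
  rw <- grid_ttest(tab, var_equal = FALSE)
  tw <- t.test(a, b, alternative = "greater")
  expect_equal(rw$t[1, 1], unname(tw$statistic))
  expect_equal(rw$p_right[1, 1], tw$p.value)
  # identical distributions: t near 0 in expectation
  set.seed(4)
  x <- rnorm(200)
  tab2 <- toy_drop_table(array(x, c(200, 1, 1)),
                         data.frame(subject = 1, item = 1:200,
                                    configuration = "0011",
                                    recalled_s3 = rep(0:1, 100)))
  expect_lt(abs(grid_ttest(tab2)$t[1, 1]), 2.5)
  # planted shift: right-tail p < 0.001
  x3 <- c(rnorm(50) + 3, rnorm(50))
  tab3 <- toy_drop_table(array(x3, c(100, 1, 1)),
                         data.frame(subject = 1, item = 1:100,
                                    configuration = "0011",
                                    recalled_s3 = rep(c(1, 0), each = 50)))
  expect_lt(grid_ttest(tab3)$p_right[1, 1], 0.001)
  # an empty class errors
  tab4 <- tab3; tab4$items$recalled_s3 <- 1
  expect_error(grid_ttest(tab4), "class")
})

test_that("KS diagnostic accepts normal samples, rejects uniform, skips tiny ones", {
  set.seed(6)
  r <- ks_normality_check(list(remembered = rnorm(500),
                               forgotten = rnorm(400, 2, 3)))
  expect_true(all(r$p > 0.01))
  ru <- ks_normality_check(list(u = runif(5000)))
  expect_lt(ru$p, 0.001)
  expect_warning(rs <- ks_normality_check(list(tiny = rnorm(5))), "skipped")
  expect_true(is.na(rs$p))
})

test_that("cluster finding uses 4-connectivity, not diagonal adjacency", {
  p <- matrix(1, 3, 3)
  p[1, 1] <- 0.01; p[2, 2] <- 0.01   # touch only diagonally
  cl <- find_clusters(p, 0.10)
  expect_equal(sort(cl$sizes), c(1, 1))   # two clusters of size 1
  # all above threshold: no clusters
  expect_equal(length(find_clusters(matrix(1, 4, 4), 0.10)$sizes), 0)
  # a plus-shaped component stays one cluster of size 5
  m <- matrix(FALSE, 5, 5); m[3, 2:4] <- TRUE; m[2:4, 3] <- TRUE
  expect_equal(find_clusters(m)$sizes, 5)
})

test_that("cluster labeling agrees with a flood-fill oracle on random masks", {
  set.seed(12)
  for (rep in 1:100) {
    mask <- matrix(runif(100) < 0.4, 10, 10)
    got <- find_clusters(mask)
    ref <- flood_fill_oracle(mask)
    expect_identical(canonical_components(got$labels),
                     canonical_components(ref))
    expect_equal(sort(got$sizes),
                 sort(as.vector(table(ref[ref > 0]))),
                 ignore_attr = TRUE)
  }
})

test_that("family-wise p uses the add-one convention and flags planted effects", {
  set.seed(15)
  n <- 400
  drops <- array(rnorm(n * 4 * 5), c(n, 4, 5))
  g <- rep(c(1, 0), each = n / 2)
  drops[g == 1, 2:3, 2:4] <- drops[g == 1, 2:3, 2:4] + 0.4  # planted block
  tab <- toy_drop_table(drops, data.frame(subject = rep(1:4, n / 4), item = 1:n,
                                          configuration = "0011",
                                          recalled_s3 = g))
  res <- cluster_permutation(tab, n_perm = 200, seed = 3)
  big <- which.max(res$clusters$size)
  expect_equal(res$clusters$fw_p[big], 1 / 201)   # beats every permutation
  expect_true(res$clusters$significant[big])
  expect_gte(res$clusters$size[big], 6)
  # every family-wise p obeys the add-one estimator against the stored null
  expect_equal(res$clusters$fw_p,
               (1 + vapply(res$clusters$size,
                           function(s) sum(res$null_max_sizes >= s), 0L)) /
                 (200 + 1))
  # the significant squares cover the planted block
  sig <- significant_squares(res)
  expect_true(all(sig[2:3, 2:4]))
  # family-wise p values always in (0, 1]
  expect_true(all(res$clusters$fw_p > 0 & res$clusters$fw_p <= 1))
  expect_warning(cluster_permutation(tab, n_perm = 50, seed = 1), "unstable")
})

test_that("the permutation null is invariant to item ordering", {
  set.seed(20)
  n <- 60
  drops <- array(rnorm(n * 3 * 3), c(n, 3, 3))
  items <- data.frame(subject = rep(1:3, n / 3), item = 1:n,
                      configuration = "0011", recalled_s3 = rep(0:1, n / 2))
  tab <- toy_drop_table(drops, items)
  res1 <- cluster_permutation(tab, n_perm = 150, seed = 5)
  perm <- sample(n)
  tab2 <- toy_drop_table(drops[perm, , , drop = FALSE],
                         items[perm, ])
  res2 <- cluster_permutation(tab2, n_perm = 150, seed = 5)
  # observed t grids identical up to the reordering; same cluster sizes
  expect_equal(res1$t, res2$t)
  expect_equal(sort(res1$clusters$size), sort(res2$clusters$size))
})

test_that("subject bootstrap reports inclusion frequencies with skipped-draw handling", {
  set.seed(25)
  n <- 400
  drops <- array(rnorm(n * 3 * 4), c(n, 3, 4))
  g <- rep(c(1, 0), n / 2)
  drops[g == 1, 1:2, 1:3] <- drops[g == 1, 1:2, 1:3] + 0.4
  tab <- toy_drop_table(drops, data.frame(subject = rep(1:4, each = n / 4),
                                          item = 1:n, configuration = "0011",
                                          recalled_s3 = g))
  boot <- subject_bootstrap(tab, n_boot = 25, n_perm = 100, seed = 7)
  expect_true(all(boot$freq >= 0 & boot$freq <= 1))
  expect_equal(boot$n_valid + boot$n_skipped, 25)
  # strong planted effect: in-block frequency near 1
  expect_gt(mean(boot$freq[1:2, 1:3]), 0.8)
  expect_lt(mean(boot$freq[3, 4]), 0.3)
  expect_error(subject_bootstrap(toy_drop_table(
    drops[1:10, , , drop = FALSE],
    data.frame(subject = 1, item = 1:10, configuration = "0011",
               recalled_s3 = g[1:10])), n_boot = 5), "2 subjects")
})
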