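test_that("sliding-window features equal the mean over the half-open window", {
  sfreq <- 512
  dt <- 1000 / sfreq
  times <- seq(-100, 1000 - dt / 2, by = dt)
  nt <- length(times)
  set.seed(3)
  data <- array(rnorm(4 * 3 * nt), c(4, 3, nt))
  ep <- epoch_set(data, times, sfreq)
  wf <- suppressMessages(sliding_window_features(ep, 50, 20))
  # brute-force index-enumeration oracle
  for (k in sample(seq_along(wf$start_times), 8)) {
    idx <- integer(0)
    for (i in seq_len(nt))
      if (times[i] >= wf$start_times[k] && times[i] < wf$start_times[k] + 50)
        idx <- c(idx, i)
    for (tr in 1:4) for (ch in 1:3)
      expect_equal(wf$features[tr, ch, k], mean(data[tr, ch, idx]))
  }
  # every window lies fully inside the epoch
  expect_true(all(wf$start_times + 50 <= max(times) + dt + 1e-9))
})

test_that("constant and ramp epochs give the closed-form window means", {
  sfreq <- 200    # 5 ms sampling: windows hold an odd sample count symmetric
  dt <- 1000 / sfreq
  times <- seq(0, 500 - dt / 2, by = dt)
  const <- epoch_set(array(7, c(1, 1, length(times))), times, sfreq)
  wfc <- suppressMessages(sliding_window_features(const, 50, 20))
  expect_true(all(abs(wfc$features - 7) < 1e-12))
  ramp <- epoch_set(array(times, c(1, 1, length(times))), times, sfreq)
  wfr <- suppressMessages(sliding_window_features(ramp, 50, 20))
  # mean of an arithmetic sequence = value at the midpoint of the sampled
  # window [t, t + 50 - dt]
  expected <- wfr$start_times + (50 - dt) / 2
  expect_equal(as.vector(wfr$features[1, 1, ]), expected)
})

test_that("windows that do not fit are excluded with a message", {
  times <- seq(0, 95, by = 5)
  ep <- epoch_set(array(0, c(1, 1, length(times))), times, 200)
  expect_message(wf <- sliding_window_features(ep, 50, 20), "excluded")
  expect_equal(wf$start_times, c(0, 20, 40))   # 60..95 window would overrun
})

test_that("cross-validated decoding separates planted blobs and stays at chance under shuffling", {
  set.seed(11)
  n <- 60
  x <- rbind(matrix(rnorm(n / 2 * 6, mean = 3), n / 2, 6),
             matrix(rnorm(n / 2 * 6, mean = -3), n / 2, 6))
  y <- rep(c("a", "b"), each = n / 2)
  expect_gte(crossval_decode(x, y, seed = 1), 0.95)
  # channel permutation applied to all trials leaves accuracy unchanged
  perm <- sample(6)
  expect_equal(crossval_decode(x[, perm], y, seed = 1),
               crossval_decode(x, y, seed = 1))
  # shuffled labels: accuracy inside the binomial 99% band around 0.5
  accs <- vapply(1:20, function(i) {
    ys <- withr::with_seed(i, sample(y))
    crossval_decode(x, ys, seed = i)
  }, 0)
  band <- qnorm(0.995) * sqrt(0.25 / n)
  expect_lt(abs(mean(accs) - 0.5), band)
  expect_error(crossval_decode(x, rep("a", n)), "two classes")
})

test_that("within-subject permutation p follows the add-one convention", {
  set.seed(2)
  n <- 40
  x <- rbind(matrix(rnorm(n / 2 * 4, mean = 4), n / 2, 4),
             matrix(rnorm(n / 2 * 4, mean = -4), n / 2, 4))
  y <- rep(0:1, each = n / 2)
  r <- within_subject_permutation_p(x, y, n_perm = 25, seed = 3)
  expect_equal(r$p, 1 / 26)    # observed beats every permutation
  expect_gt(r$p, 0)
  # pure noise: p bounded in (0, 1] and typically large
  xn <- matrix(rnorm(n * 4), n, 4)
  rn <- within_subject_permutation_p(xn, sample(y), n_perm = 25, seed = 4)
  expect_true(rn$p > 0 && rn$p <= 1)
  # accuracy below the permutation median implies p > 0.5
  if (rn$observed < median(rn$perm_acc)) expect_gt(rn$p, 0.5)
})

test_that("group significance combines p values by the inverse-normal route", {
  # oracle: direct formula evaluation on jittered strong p values
  p <- matrix(c(0.0105, 0.0150, 0.0205, 0.0118,
                0.5, 0.45, 0.55, 0.52), nrow = 4)
  gs <- group_significance(p, alpha = 0.001, p_clip = 1 / 101)
  z <- qnorm(1 - p)
  for (j in 1:2) {
    tt <- t.test(z[, j], mu = 0, alternative = "greater")
    expect_equal(gs$group_p[j], tt$p.value)
  }
  expect_equal(gs$threshold, 0.001 / 2)
  expect_true(gs$mask[1])
  expect_false(gs$mask[2])
  # all subjects at p = 0.5 gives z = 0: not significant
  gs0 <- group_significance(matrix(0.5, 5, 3))
  expect_false(any(gs0$mask))
  expect_error(group_significance(matrix(0.1, 2, 4)), "3 subjects")
  # 55 timepoints at alpha 0.001 gives the 0.001/55 Bonferroni threshold
  expect_equal(group_significance(matrix(0.5, 5, 55))$threshold, 0.001 / 55)
})

test_that("window selection bridges short dips and prefers the longest early run", {
  starts <- seq(0, 980, by = 20)
  # criteria true on 80..600 ms except a 100-200 ms dip (bridged at 120 ms)
  acc <- rep(0.5, length(starts))
  sdv <- rep(0.01, length(starts))
  mask <- starts >= 80 & starts <= 600
  acc[mask] <- 0.65
  dip <- starts >= 120 & starts <= 180
  acc[dip] <- 0.5        # accuracy criterion fails inside the dip
  win <- select_time_window(starts, acc, sdv, mask, bridge_ms = 120)
  expect_equal(win$t_start, 80)
  expect_equal(win$t_end, 600)
  # without bridging the dip splits the window and the longer run wins
  win0 <- select_time_window(starts, acc, sdv, mask, bridge_ms = 0)
  expect_equal(win0$t_start, 200)
  expect_equal(win0$t_end, 600)
  # single qualifying timepoint: degenerate one-point window
  mask1 <- starts == 300
  acc1 <- ifelse(mask1, 0.7, 0.5)
  win1 <- select_time_window(starts, acc1, sdv, mask1)
  expect_equal(win1$t_start, 300)
  expect_equal(win1$t_end, 300)
  # tie between two runs separated by a long gap: earlier run returned
  mask2 <- (starts >= 100 & starts <= 200) | (starts >= 600 & starts <= 700)
  acc2 <- ifelse(mask2, 0.7, 0.5)
  win2 <- select_time_window(starts, acc2, sdv, mask2, bridge_ms = 120)
  expect_equal(win2$t_start, 100)
  # enumeration oracle for the no-bridge run structure
  r <- rle(mask2)
  expect_equal(sum(mask2), sum(r$lengths[r$values]))
  # empty mask: explicit no-window result
  none <- select_time_window(starts, acc, sdv, rep(FALSE, length(starts)))
  expect_equal(none$index, integer(0))
  expect_null(none$t_start)
})

test_that("decoding recovers the planted signal window across subjects", {
  cfg <- simulation_config(n_subjects = 4, n_channels = 8, sampling_rate = 64,
                           epoch_span = c(-100, 500), n_categories = 5,
                           n_exemplars_per_category = 6,
                           signal_window = c(100, 300), effect_size = 4,
                           seed = 21)
  s1 <- simulate_session1(cfg)
  acc <- t(vapply(1:4, function(s) {
    wf <- sliding_window_features(
      subset_trials(s1$epochs, s1$epochs$metadata$subject == s), 50, 40)
    decode_sliding(wf, wf$metadata$condition, seed = s)$accuracy
  }, numeric(14)))
  starts <- seq(-100, 420, by = 40)
  ga <- colMeans(acc)
  inside <- starts >= 100 & starts <= 240  # windows inside the signal span
  outside <- starts + 50 <= 100            # windows ending before the signal
  expect_gt(min(ga[inside]), max(ga[outside]))
  expect_gt(max(ga), 0.9)
  expect_lt(abs(mean(ga[outside]) - 0.5), 0.1)
})
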