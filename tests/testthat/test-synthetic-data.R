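test_that("identical seed and config give a bit-identical dataset", {
  cfg <- small_config()
  a <- simulate_session1(cfg)
  b <- simulate_session1(cfg)
  expect_identical(a$epochs$data, b$epochs$data)
  expect_identical(a$ground_truth, b$ground_truth)
  a2 <- simulate_session2(cfg)
  b2 <- simulate_session2(cfg)
  expect_identical(a2$epochs$data, b2$epochs$data)
  expect_identical(a2$behavior, b2$behavior)
  c2 <- simulate_session2(simulation_config(
    n_subjects = 2, n_channels = 8, sampling_rate = 64,
    epoch_span = c(-100, 500), n_categories = 5,
    n_exemplars_per_category = 6, n_items_s2 = 30,
    signal_window = c(100, 300), effect_size = 3,
    drop_memory_coupling = 6, seed = 43))
  expect_false(identical(a2$epochs$data, c2$epochs$data))
})

test_that("session 1 design yields one balanced trial per design cell", {
  cfg <- small_config()
  s1 <- simulate_session1(cfg)
  n_expected <- cfg$n_categories * cfg$n_exemplars_per_category * 2
  for (s in 1:2) {
    md <- s1$ground_truth[s1$ground_truth$subject == s, ]
    expect_equal(nrow(md), n_expected)
    expect_equal(as.vector(table(md$condition)), c(n_expected / 2, n_expected / 2))
    # each category x exemplar x condition cell appears exactly once
    expect_equal(anyDuplicated(md[, c("category", "exemplar", "condition")]), 0L)
  }
})

test_that("class-conditional mean difference is zero outside the signal window", {
  cfg <- simulation_config(n_subjects = 1, n_channels = 4, sampling_rate = 64,
                           epoch_span = c(-100, 500), n_categories = 4,
                           n_exemplars_per_category = 5,
                           signal_window = c(100, 300), effect_size = 5,
                           noise_model = list(sd = 1e-12), seed = 2)
  s1 <- simulate_session1(cfg)
  hi <- apply(s1$epochs$data[s1$ground_truth$condition == "high", , ], c(2, 3), mean)
  lo <- apply(s1$epochs$data[s1$ground_truth$condition == "low", , ], c(2, 3), mean)
  diffmap <- hi - lo
  outside <- s1$epochs$times < 100 | s1$epochs$times > 300
  expect_lt(max(abs(diffmap[, outside])), 1e-9)
  # inside the window the separation equals effect_size * topography x envelope
  env <- compdrop:::signal_envelope(cfg)
  expected <- outer(cfg$signal_topography, env) * cfg$effect_size
  expect_equal(diffmap, expected, tolerance = 1e-6)
})

test_that("zero effect size leaves the two classes exchangeable", {
  cfg <- simulation_config(n_subjects = 1, n_channels = 6, sampling_rate = 64,
                           epoch_span = c(-100, 400), n_categories = 6,
                           n_exemplars_per_category = 8, effect_size = 0,
                           signal_window = c(100, 300), seed = 9)
  s1 <- simulate_session1(cfg)
  wf <- sliding_window_features(s1$epochs)
  accs <- vapply(seq_along(wf$start_times), function(k)
    crossval_decode(compdrop:::features_at(wf, k), wf$metadata$condition,
                    seed = k), 0)
  # CV accuracy stays inside a generous binomial band around chance
  expect_true(all(abs(accs - 0.5) < 0.2))
  expect_lt(abs(mean(accs) - 0.5), 0.06)
})

test_that("deterministic learning curve forces the 0011 configuration", {
  cfg <- simulation_config(n_subjects = 1, n_channels = 4, sampling_rate = 64,
                           epoch_span = c(-100, 400), n_items_s2 = 20,
                           recall_learning_curve = c(0, 0, 1, 1),
                           ability_sd = 0, seed = 3)
  s2 <- simulate_session2(cfg, eeg = FALSE)
  expect_true(all(s2$ground_truth$configuration == "0011"))
  expect_true(all(s2$ground_truth$first_correct == 3))
})

test_that("planted drop follows the first-correct-minus-final rule and stays bounded", {
  cfg <- small_config()
  gt <- simulate_session2(cfg, eeg = FALSE)$ground_truth
  lat <- as.matrix(gt[, paste0("latent_r", 1:4)])
  expect_true(all(lat >= 0 & lat <= 1))
  retained <- !is.na(gt$planted_drop)
  expect_equal(gt$planted_drop[retained],
               lat[cbind(which(retained), gt$first_correct[retained])] -
                 lat[retained, 4])
})

test_that("delayed recall is calibrated to the logistic link in the planted drop", {
  cfg <- simulation_config(n_subjects = 60, n_items_s2 = 60,
                           drop_memory_coupling = 6, seed = 8)
  gt <- simulate_session2(cfg, eeg = FALSE)$ground_truth
  p_model <- plogis(cfg$recall_base_logodds +
                    cfg$drop_memory_coupling * (gt$drop_any - cfg$drop_centering))
  bins <- cut(p_model, quantile(p_model, 0:5 / 5), include.lowest = TRUE)
  emp <- tapply(gt$recalled_s3, bins, mean)
  pred <- tapply(p_model, bins, mean)
  n_bin <- table(bins)
  # each quintile's empirical rate within ~3 binomial SEs of the link
  expect_true(all(abs(emp - pred) < 3 * sqrt(pred * (1 - pred) / n_bin) + 0.01))
})

test_that("reaction times sit above the response delay with dominant item variance", {
  cfg <- simulation_config(n_subjects = 6, n_items_s2 = 40, seed = 5)
  beh <- simulate_session2(cfg, eeg = FALSE)$behavior
  expect_true(all(beh$rt_s > cfg$rt_model$delay_s))
  lrt <- log(beh$rt_s - cfg$rt_model$delay_s)
  fit <- stats::aov(lrt ~ factor(paste(beh$subject, beh$item)) + factor(beh$round))
  ms <- summary(fit)[[1]]$`Mean Sq`
  expect_gt(ms[1], ms[2])  # item variance dominates the round effect
})

test_that("an invalid spatial covariance is rejected at configuration time", {
  bad <- matrix(c(1, 2, 2, 1), 2, 2)  # not positive definite
  expect_error(simulation_config(n_channels = 2, noise_model = list(spatial = bad)),
               "covariance")
  expect_error(simulation_config(n_subjects = 0), "positive")
  expect_error(simulation_config(recall_learning_curve = c(0.2, 0.4, 0.6, 1.3)),
               "probabilities")
})

test_that("write_dataset / read_dataset round-trips losslessly and validates columns", {
  cfg <- simulation_config(n_subjects = 1, n_channels = 4, sampling_rate = 64,
                           epoch_span = c(-100, 300), n_items_s2 = 6, seed = 4)
  s2 <- simulate_session2(cfg)
  dir <- file.path(tempdir(), "ds_roundtrip")
  write_dataset(s2$epochs, s2$behavior, dir)
  back <- read_dataset(dir)
  expect_identical(back$epochs$data, s2$epochs$data)
  expect_identical(back$epochs$times, s2$epochs$times)
  expect_equal(back$behavior$rt_s, s2$behavior$rt_s)
  expect_equal(back$behavior$correct, s2$behavior$correct)
  bad <- s2$behavior[, setdiff(names(s2$behavior), "rt_s")]
  expect_error(write_dataset(s2$epochs, bad, dir), "rt_s")
})

test_that("the shipped 2-subject synthetic behavior fixture loads quickly", {
  path <- system.file("extdata", "behavior_2subj_synthetic.tsv",
                      package = "compdrop")
  expect_true(nzchar(path))
  t0 <- Sys.time()
  beh <- utils::read.table(path, sep = "\t", header = TRUE)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
  expect_setequal(names(beh), c("subject", "item", "round", "correct",
                                "rt_s", "recalled_s3"))
  expect_equal(nrow(beh), 2 * 60 * 4)
  # fixture is the generator's own output at a fixed seed
  cfg <- simulation_config(n_subjects = 2, seed = 20240915)
  expect_equal(simulate_session2(cfg, eeg = FALSE)$behavior$correct, beh$correct)
})
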