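#' Simulation configuration for synthetic EEG + behavior datasets
#'
#' Defines the experimental design and the planted ground truth of the
#' synthetic datasets: a Session 1 "competition localizer" (balanced
#' high- vs low-competition cued recall, one trial per category x
#' exemplar x condition cell) and a Session 2/3 vocabulary-learning task
#' (four study+test rounds per item, delayed recall one week later).
#' Defaults follow the study design the analysis targets: 40 subjects,
#' 64 channels at 512 Hz, 19 categories x 8 exemplars (304 localizer
#' trials per subject), 60 vocabulary items x 4 rounds.
#'
#' @param n_subjects number of simulated subjects.
#' @param n_channels number of EEG channels.
#' @param sampling_rate sampling rate in Hz.
#' @param epoch_span c(pre, post) epoch limits in ms around stimulus onset.
#' @param n_categories,n_exemplars_per_category Session 1 stimulus design;
#'   the test phase shows every category x exemplar x condition cell once,
#'   giving `n_categories * n_exemplars_per_category * 2` trials.
#' @param n_items_s2 number of vocabulary items in Session 2.
#' @param n_rounds number of study+test rounds in Session 2.
#' @param signal_window c(start, end) ms interval carrying the class
#'   signal; the class-conditional mean difference is exactly zero
#'   outside it.
#' @param signal_topography per-channel loading vector (unit norm
#'   recommended); default is a smooth unimodal bump over the channel
#'   index, normalized to unit norm.
#' @param effect_size scalar separating the two Session 1 class means
#'   (the between-class mean difference at the envelope peak equals
#'   `effect_size * signal_topography`).
#' @param drop_memory_coupling logistic slope linking the planted
#'   competition drop of an item to its delayed-recall log-odds.
#' @param drop_centering constant subtracted from the drop inside the
#'   delayed-recall link (the approximate expected planted drop), so the
#'   default intercept gives near-balanced delayed recall, as observed
#'   in this paradigm.
#' @param recall_base_logodds intercept of the delayed-recall logistic
#'   link; default 0 puts marginal delayed recall near 50%.
#' @param recall_learning_curve per-round recall probabilities (length
#'   `n_rounds`, in `[0,1]`, non-decreasing); items get an additive
#'   log-odds ability offset so learning varies across items.
#' @param ability_sd SD of the per-item recall-ability offset (log-odds).
#' @param ability_memory_coupling log-odds contribution of the per-item
#'   learning ability to delayed recall, reproducing the paradigm's
#'   strong dependence of one-week recall on how often an item was
#'   answered correctly during learning.
#' @param competition_start_range range of the uniform initial latent
#'   competition level.
#' @param competition_decrement c(mean, sd) of the per-round latent
#'   competition decrement (negative draws truncated at 0), giving
#'   monotone-in-expectation decline with across-item variance in drop.
#' @param noise_model list: `sd` noise scale, `spatial_decay` length
#'   scale of the exponential inter-channel correlation (in channel-index
#'   units), `ar1` temporal lag-1 autocorrelation, or `spatial` an
#'   explicit channel covariance matrix (must be positive semi-definite).
#' @param rt_model list for the log-normal reaction-time model:
#'   `delay_s` enforced response delay, `meanlog`, `sdlog_item` (item
#'   random effect, dominating), `sdlog_trial`, `round_slope` (weak
#'   per-round decrease on the log scale).
#' @param seed integer; identical seed + config give an identical dataset.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 40,
                              n_channels = 64,
                              sampling_rate = 512,
                              epoch_span = c(-100, 1000),
                              n_categories = 19,
                              n_exemplars_per_category = 8,
                              n_items_s2 = 60,
                              n_rounds = 4,
                              signal_window = c(100, 500),
                              signal_topography = NULL,
                              effect_size = 1,
                              drop_memory_coupling = 4,
                              drop_centering = 0.15,
                              recall_base_logodds = 0,
                              recall_learning_curve = c(0.30, 0.50, 0.65, 0.78),
                              ability_sd = 1,
                              ability_memory_coupling = 0.8,
                              competition_start_range = c(0.55, 0.95),
                              competition_decrement = c(0.08, 0.05),
                              noise_model = list(sd = 1, spatial_decay = 8, ar1 = 0.3),
                              rt_model = list(delay_s = 2, meanlog = 0,
                                              sdlog_item = 0.6, sdlog_trial = 0.25,
                                              round_slope = -0.05),
                              seed = 1) {
  counts <- c(n_subjects, n_channels, n_categories, n_exemplars_per_category,
              n_items_s2, n_rounds)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all design counts must be positive integers")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (length(epoch_span) != 2 || epoch_span[1] >= epoch_span[2])
    stop("epoch_span must be c(pre, post) with pre < post")
  if (length(recall_learning_curve) != n_rounds)
    stop("recall_learning_curve must have one probability per round")
  if (any(recall_learning_curve < 0 | recall_learning_curve > 1))
    stop("recall probabilities must lie in [0, 1]")
  if (is.unsorted(recall_learning_curve))
    warning("recall_learning_curve is not non-decreasing across rounds")
  if (is.null(signal_topography)) {
    ch <- seq_len(n_channels)
    topo <- exp(-((ch - 0.35 * n_channels) / (0.18 * n_channels))^2)
    signal_topography <- topo / sqrt(sum(topo^2))
  }
  if (length(signal_topography) != n_channels)
    stop("signal_topography must have one loading per channel")
  nm <- utils::modifyList(list(sd = 1, spatial_decay = 8, ar1 = 0.3,
                               spatial = NULL), noise_model)
  if (!is.null(nm$spatial)) {
    ok <- tryCatch({ chol(nm$spatial); TRUE }, error = function(e) FALSE)
    if (!ok) stop("noise_model$spatial is not a valid (positive definite) covariance")
  }
  if (abs(nm$ar1) >= 1) stop("noise_model$ar1 must lie in (-1, 1)")
  cfg <- list(n_subjects = n_subjects, n_channels = n_channels,
              sampling_rate = sampling_rate, epoch_span = epoch_span,
              n_categories = n_categories,
              n_exemplars_per_category = n_exemplars_per_category,
              n_items_s2 = n_items_s2, n_rounds = n_rounds,
              signal_window = signal_window,
              signal_topography = signal_topography,
              effect_size = effect_size,
              drop_memory_coupling = drop_memory_coupling,
              drop_centering = drop_centering,
              recall_base_logodds = recall_base_logodds,
              recall_learning_curve = recall_learning_curve,
              ability_sd = ability_sd,
              ability_memory_coupling = ability_memory_coupling,
              competition_start_range = competition_start_range,
              competition_decrement = competition_decrement,
              noise_model = nm,
              rt_model = utils::modifyList(
                list(delay_s = 2, meanlog = 0, sdlog_item = 0.6,
                     sdlog_trial = 0.25, round_slope = -0.05), rt_model),
              seed = as.integer(seed))
  structure(cfg, class = "simulation_config")
}

# Time axis and signal envelope implied by a config. The envelope is a
# raised cosine supported exactly on signal_window (zero outside).
sim_time_axis <- function(config) {
  dt <- 1000 / config$sampling_rate
  seq(config$epoch_span[1], config$epoch_span[2] - dt / 2, by = dt)
}

signal_envelope <- function(config, times = sim_time_axis(config)) {
  w <- config$signal_window
  env <- numeric(length(times))
  inside <- times >= w[1] & times <= w[2]
  env[inside] <- 0.5 - 0.5 * cos(2 * pi * (times[inside] - w[1]) / (w[2] - w[1]))
  env
}

# Channel covariance Cholesky factor (upper triangular R with Sigma = R'R).
spatial_chol <- function(config) {
  nm <- config$noise_model
  if (!is.null(nm$spatial)) {
    sigma <- nm$spatial
  } else {
    idx <- seq_len(config$n_channels)
    sigma <- nm$sd^2 * exp(-abs(outer(idx, idx, "-")) / nm$spatial_decay)
  }
  chol(sigma)
}

# Correlated noise for one subject: AR(1) along time (unit marginal
# variance in the stationary regime), exponential-decay correlation
# across channels. Returns trials x channels x time.
sim_noise <- function(config, n_tr, n_time, R) {
  rho <- config$noise_model$ar1
  z <- matrix(stats::rnorm(n_time * n_tr * config$n_channels,
                           sd = sqrt(1 - rho^2)),
              n_time, n_tr * config$n_channels)
  e <- as.matrix(stats::filter(z, rho, method = "recursive"))
  arr <- array(e, c(n_time, n_tr, config$n_channels))
  m <- matrix(aperm(arr, c(2, 1, 3)), n_tr * n_time, config$n_channels) %*% R
  aperm(array(m, c(n_tr, n_time, config$n_channels)), c(1, 3, 2))
}

#' Simulate the Session 1 competition localizer
#'
#' Generates, per subject, one epoch per category x exemplar x condition
#' cell (balanced high- vs low-competition classes, randomly
#' interleaved). The class-conditional mean is `+/- effect_size/2 *
#' signal_topography` times a raised-cosine temporal envelope supported
#' only inside `signal_window`, added to spatially and temporally
#' correlated Gaussian noise.
#'
#' @param config a [simulation_config()].
#' @return list with `epochs` (an [epoch_set()] pooled over subjects,
#'   metadata columns `subject`, `condition`, `category`, `exemplar`) and
#'   `ground_truth` (per-trial data.frame with the class labels).
#' @export
simulate_session1 <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  times <- sim_time_axis(config)
  env <- signal_envelope(config, times)
  R <- spatial_chol(config)
  n_per <- config$n_categories * config$n_exemplars_per_category * 2L
  half <- config$effect_size / 2
  mean_hi <- outer(config$signal_topography, env) * half    # ch x time
  blocks <- vector("list", config$n_subjects)
  meta <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    withr::with_seed(child_seed(config$seed, 1000L + s), {
      design <- expand.grid(exemplar = seq_len(config$n_exemplars_per_category),
                            category = seq_len(config$n_categories),
                            condition = c("high", "low"),
                            stringsAsFactors = FALSE)
      design <- design[sample(nrow(design)), c("category", "exemplar", "condition")]
      rownames(design) <- NULL
      x <- sim_noise(config, n_per, length(times), R)
      sign_vec <- ifelse(design$condition == "high", 1, -1)
      for (i in seq_len(n_per))
        x[i, , ] <- x[i, , ] + sign_vec[i] * mean_hi
      blocks[[s]] <- x
      meta[[s]] <- cbind(subject = s, design)
    })
  }
  data <- do.call(abind3, blocks)
  metadata <- do.call(rbind, meta)
  metadata$trial <- seq_len(nrow(metadata))
  list(epochs = epoch_set(data, times, config$sampling_rate,
                          metadata = metadata),
       ground_truth = metadata)
}

# rbind for 3-d arrays along the trial dimension
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- array(NA_real_, c(sum(vapply(xs, function(x) dim(x)[1], 0L)), d[2], d[3]))
  at <- 0L
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

#' Simulate the Session 2 learning task and Session 3 delayed recall
#'
#' Per item, a latent competition level in `[0,1]` declines across
#' rounds (monotone in expectation, with item-level variance). Retrieval
#' epochs for item i, round r carry the mean pattern
#' `effect_size * (latent - 0.5) * signal_topography x envelope`; study
#' epochs carry a round-independent neutral pattern (latent fixed at
#' 0.5), so any apparent drop on study trials is noise. Per-round
#' correctness follows `recall_learning_curve` shifted by a per-item
#' ability; the delayed-recall label is drawn with log-odds
#' `recall_base_logodds + drop_memory_coupling * (drop - drop_centering)`,
#' where the drop is the latent level at the first-correct round minus
#' the latent level at the final round (first round if never correct).
#' Reaction times are log-normal with a dominant item random effect and a
#' weak negative round slope, on top of the enforced response delay.
#'
#' @param config a [simulation_config()].
#' @param ground_truth_s1 optional Session 1 ground truth (unused by the
#'   generative model; accepted so the two sessions can be chained).
#' @param eeg logical; set `FALSE` to generate behavior and ground truth
#'   only (cheap, e.g. for design-count checks at full scale).
#' @param include_study logical; also simulate the study-block epochs
#'   used by the study-trial control analysis.
#' @return list with `epochs` (an [epoch_set()], or `NULL` when
#'   `eeg = FALSE`; metadata columns `subject`, `item`, `round`,
#'   `trial_type`), `behavior` (long data.frame: `subject`, `item`,
#'   `round`, `correct`, `rt_s`, `recalled_s3`) and `ground_truth`
#'   (per-item data.frame with latent levels, planted drop, configuration).
#' @export
simulate_session2 <- function(config, ground_truth_s1 = NULL, eeg = TRUE,
                              include_study = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  times <- sim_time_axis(config)
  env <- signal_envelope(config, times)
  if (eeg) R <- spatial_chol(config)
  ni <- config$n_items_s2; nr <- config$n_rounds
  rtm <- config$rt_model
  base_logit <- stats::qlogis(config$recall_learning_curve)
  gt_list <- beh_list <- ep_list <- meta_list <- list()
  for (s in seq_len(config$n_subjects)) {
    withr::with_seed(child_seed(config$seed, 2000L + s), {
      start <- stats::runif(ni, config$competition_start_range[1],
                            config$competition_start_range[2])
      dec <- matrix(pmax(0, stats::rnorm(ni * (nr - 1),
                                         config$competition_decrement[1],
                                         config$competition_decrement[2])),
                    ni, nr - 1)
      dec_cum <- if (nr == 2) dec else t(apply(dec, 1, cumsum))
      latent <- clip(cbind(start, start - dec_cum), 0.02, 0.98)
      colnames(latent) <- paste0("latent_r", seq_len(nr))
      ability <- stats::rnorm(ni, 0, config$ability_sd)
      p_correct <- stats::plogis(outer(ability, base_logit, "+"))
      correct <- matrix(stats::runif(ni * nr) < p_correct, ni, nr)
      first_correct <- apply(correct, 1, function(z) {
        w <- which(z); if (length(w)) w[1] else NA_integer_
      })
      retained <- !is.na(first_correct) & correct[, nr]
      ref_round <- ifelse(is.na(first_correct), 1L, first_correct)
      drop_any <- latent[cbind(seq_len(ni), ref_round)] - latent[, nr]
      planted_drop <- ifelse(retained, drop_any, NA_real_)
      recalled <- stats::runif(ni) < stats::plogis(
        config$recall_base_logodds +
        config$drop_memory_coupling * (drop_any - config$drop_centering) +
        config$ability_memory_coupling * ability)
      item_re <- stats::rnorm(ni, 0, rtm$sdlog_item)
      rt <- rtm$delay_s + exp(
        rtm$meanlog + item_re[rep(seq_len(ni), nr)] +
        rtm$round_slope * (rep(seq_len(nr), each = ni) - 1) +
        stats::rnorm(ni * nr, 0, rtm$sdlog_trial))
      rt <- matrix(rt, ni, nr)
      config_str <- apply(correct, 1, function(z) paste(as.integer(z), collapse = ""))
      gt_list[[s]] <- data.frame(subject = s, item = seq_len(ni), latent,
                                 first_correct = first_correct,
                                 configuration = config_str,
                                 planted_drop = planted_drop,
                                 drop_any = drop_any,
                                 recalled_s3 = as.integer(recalled))
      beh_list[[s]] <- data.frame(
        subject = s,
        item = rep(seq_len(ni), nr),
        round = rep(seq_len(nr), each = ni),
        correct = as.integer(correct),
        rt_s = as.numeric(rt),
        recalled_s3 = rep(as.integer(recalled), nr))
      if (eeg) {
        amp_test <- config$effect_size * (as.numeric(latent) - 0.5)
        amps <- amp_test
        type <- rep("retrieval", ni * nr)
        if (include_study) {
          amps <- c(amp_test, rep(0, ni * nr))   # study: latent pinned at 0.5
          type <- c(type, rep("study", ni * nr))
        }
        n_tr <- length(amps)
        x <- sim_noise(config, n_tr, length(times), R)
        base <- outer(config$signal_topography, env)
        for (i in seq_len(n_tr))
          if (amps[i] != 0) x[i, , ] <- x[i, , ] + amps[i] * base
        ep_list[[s]] <- x
        meta_list[[s]] <- data.frame(
          subject = s,
          item = rep(rep(seq_len(ni), nr), times = if (include_study) 2 else 1),
          round = rep(rep(seq_len(nr), each = ni), times = if (include_study) 2 else 1),
          trial_type = type)
      }
    })
  }
  epochs <- NULL
  if (eeg) {
    data <- do.call(abind3, ep_list)
    metadata <- do.call(rbind, meta_list)
    metadata$trial <- seq_len(nrow(metadata))
    epochs <- epoch_set(data, times, config$sampling_rate, metadata = metadata)
  }
  list(epochs = epochs,
       behavior = do.call(rbind, beh_list),
       ground_truth = do.call(rbind, gt_list))
}

#' Write / read a simulated dataset
#'
#' Serializes an epoch set plus its behavioral table to a directory:
#' `epochs.rds` (arrays and metadata, lossless), `behavior.tsv`
#' (tab-separated, documented columns `subject`, `item`, `round`,
#' `correct`, `rt_s`, `recalled_s3`), and a JSON `manifest.json` with
#' shapes for validation. The round trip is lossless.
#'
#' @param epochs an [epoch_set()] (or `NULL` for behavior-only datasets).
#' @param behavior behavioral data.frame with the documented columns.
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(epochs, behavior, path) {
  req <- c("subject", "item", "round", "correct", "rt_s", "recalled_s3")
  missing_cols <- setdiff(req, names(behavior))
  if (length(missing_cols))
    stop("behavior table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.null(epochs) && !inherits(epochs, "epoch_set"))
    stop("`epochs` must be an epoch_set (or NULL)")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(epochs)) saveRDS(epochs, file.path(path, "epochs.rds"))
  utils::write.table(behavior, file.path(path, "behavior.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(n_trials = if (is.null(epochs)) 0L else n_trials(epochs),
                   n_behavior_rows = nrow(behavior),
                   has_epochs = !is.null(epochs))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not a dataset directory (no manifest.json): ", path)
  manifest <- jsonlite::read_json(mf)
  behavior <- utils::read.table(file.path(path, "behavior.tsv"), sep = "\t",
                                header = TRUE)
  req <- c("subject", "item", "round", "correct", "rt_s", "recalled_s3")
  missing_cols <- setdiff(req, names(behavior))
  if (length(missing_cols))
    stop("behavior table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  epochs <- NULL
  if (isTRUE(manifest$has_epochs)) {
    epochs <- readRDS(file.path(path, "epochs.rds"))
    if (n_trials(epochs) != manifest$n_trials)
      stop("manifest/epoch shape mismatch in ", path)
  }
  list(epochs = epochs, behavior = behavior)
}
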