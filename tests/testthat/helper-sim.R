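# Shared reduced-scale simulation settings and pipeline shortcuts.
# The reduced scale (few subjects/items, 8-16 channels, 64-128 Hz, short
# epochs) keeps the suite fast while preserving the statistical structure
# the analysis assumes.

small_config <- function(...) {
  simulation_config(
    n_subjects = 2, n_channels = 8, sampling_rate = 64,
    epoch_span = c(-100, 500), n_categories = 5,
    n_exemplars_per_category = 6, n_items_s2 = 30,
    signal_window = c(100, 300), effect_size = 3,
    drop_memory_coupling = 6, seed = 42, ...)
}

# Simulate both sessions and run transfer -> drop -> cluster with the
# classifiers trained directly on the planted signal window (the
# localizer's window-selection stage is validated separately).
run_drop_analysis <- function(cfg, n_perm = 200, step_ms = 40,
                              include_study = FALSE, seed = 1,
                              n_folds = 5) {
  s1 <- simulate_session1(cfg)
  s2 <- simulate_session2(cfg, eeg = TRUE, include_study = include_study)
  subjects <- sort(unique(s1$epochs$metadata$subject))
  grids <- lapply(subjects, function(s) {
    wf1 <- sliding_window_features(
      subset_trials(s1$epochs, s1$epochs$metadata$subject == s),
      window_ms = 50, step_ms = step_ms)
    in_window <- which(wf1$start_times >= cfg$signal_window[1] &
                       wf1$start_times + 50 <= cfg$signal_window[2])
    models <- train_full_models(wf1, wf1$metadata$condition,
                                train_index = in_window, positive = "high")
    wf2 <- sliding_window_features(
      subset_trials(s2$epochs, s2$epochs$metadata$subject == s),
      window_ms = 50, step_ms = step_ms)
    apply_grid(models, wf2)
  })
  grid <- structure(list(
    values = do.call(compdrop:::abind3, lapply(grids, `[[`, "values")),
    train_times = grids[[1]]$train_times,
    test_times = grids[[1]]$test_times,
    metadata = do.call(rbind, lapply(grids, `[[`, "metadata"))),
    class = "competition_grid")
  drops <- suppressMessages(competition_drop(grid, s2$behavior))
  clus <- cluster_permutation(drops, n_perm = n_perm, seed = seed)
  out <- list(s1 = s1, s2 = s2, grid = grid, drops = drops, cluster = clus)
  if (include_study) {
    drops_study <- suppressMessages(
      competition_drop(grid, s2$behavior, trial_type = "study"))
    out$cluster_study <- cluster_permutation(drops_study, n_perm = n_perm,
                                             seed = seed)
  }
  out
}

# Build a drop_table directly (for cluster-stage unit tests that do not
# need the EEG machinery).
toy_drop_table <- function(drops, items, train_times = NULL,
                           test_times = NULL) {
  d <- dim(drops)
  structure(list(drops = drops, items = items,
                 train_times = train_times %||% seq_len(d[2]),
                 test_times = test_times %||% seq_len(d[3])),
            class = "drop_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Recursive flood-fill reference for connected components (4-neighbour),
# deliberately independent of find_clusters' stack-based labeling.
flood_fill_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  lab <- 0L
  fill <- function(i, j, lab) {
    if (i < 1 || i > nr || j < 1 || j > nc) return()
    if (!mask[i, j] || labels[i, j] != 0L) return()
    labels[i, j] <<- lab
    fill(i - 1, j, lab); fill(i + 1, j, lab)
    fill(i, j - 1, lab); fill(i, j + 1, lab)
  }
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j] && labels[i, j] == 0L) {
      lab <- lab + 1L
      fill(i, j, lab)
    }
  }
  labels
}

# Canonical form for comparing two component labelings up to label order:
# the sorted list of sorted member-index sets.
canonical_components <- function(labels) {
  comp <- lapply(setdiff(sort(unique(as.vector(labels))), 0L),
                 function(l) sort(which(labels == l)))
  comp[order(vapply(comp, min, 0L))]
}
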