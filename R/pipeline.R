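#' Analysis-stage parameters for the full pipeline
#'
#' One object holding every tunable of the analysis stages (the
#' simulation has its own [simulation_config()]). Defaults follow the
#' standard analysis: 50 ms windows every 20 ms, 5-fold CV, 100
#' within-subject permutations, Bonferroni 0.001/T, cluster threshold
#' p < 0.10 with 1000 permutations at family-wise alpha 0.05.
#'
#' @param window_ms,step_ms sliding-window length and spacing.
#' @param n_folds cross-validation folds.
#' @param n_perm_localizer within-subject permutations per timepoint.
#' @param alpha_localizer initial group alpha before Bonferroni division.
#' @param sd_mult,bridge_ms window-selection parameters
#'   (see [select_time_window()]).
#' @param cluster_threshold,n_perm_cluster,cluster_alpha cluster-stage
#'   parameters.
#' @param n_boot bootstrap draws (0 disables the bootstrap stage).
#' @param n_perm_boot permutations per bootstrap draw.
#' @param n_perm_behavior permutations of the behavioral test.
#' @param C inverse ridge regularization strength.
#' @param feature `"voltage"` or `"theta"` (theta-band Hilbert power).
#' @param config_filter optional configuration strings to restrict the
#'   drop analysis to (e.g. `c("0011")`).
#' @param zscore z-score drops within subject before testing.
#' @param seed analysis seed (folds, permutations, bootstrap).
#' @return list of class `pipeline_params`.
#' @export
pipeline_params <- function(window_ms = 50, step_ms = 20, n_folds = 5,
                            n_perm_localizer = 100, alpha_localizer = 0.001,
                            sd_mult = 1, bridge_ms = 120,
                            cluster_threshold = 0.10, n_perm_cluster = 1000,
                            cluster_alpha = 0.05, n_boot = 0,
                            n_perm_boot = 200, n_perm_behavior = 1000,
                            C = 1, feature = c("voltage", "theta"),
                            config_filter = NULL, zscore = FALSE, seed = 1) {
  stopifnot(cluster_threshold > 0, cluster_threshold < 1,
            cluster_alpha > 0, cluster_alpha < 1)
  structure(list(window_ms = window_ms, step_ms = step_ms, n_folds = n_folds,
                 n_perm_localizer = n_perm_localizer,
                 alpha_localizer = alpha_localizer, sd_mult = sd_mult,
                 bridge_ms = bridge_ms, cluster_threshold = cluster_threshold,
                 n_perm_cluster = n_perm_cluster,
                 cluster_alpha = cluster_alpha, n_boot = n_boot,
                 n_perm_boot = n_perm_boot,
                 n_perm_behavior = n_perm_behavior, C = C,
                 feature = match.arg(feature),
                 config_filter = config_filter, zscore = zscore,
                 seed = as.integer(seed)),
            class = "pipeline_params")
}

stage_msg <- function(log, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(line)
  c(log, line)
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Orders the stages end to end: simulate both sessions, window the
#' epochs, run the localizer decoding with within-subject permutation
#' tests and group significance, select the discriminative window,
#' transfer full-data classifiers to Session 2 to build competition
#' grids (retrieval and study control), score competition drops, run the
#' cluster permutation test (and optionally the subject bootstrap), and
#' run the behavioral analyses. All stage outputs plus a
#' machine-readable `summary.json` and a text log are written to
#' `out_dir`. Re-running with the identical configs reproduces identical
#' results.
#'
#' @param sim_config a [simulation_config()].
#' @param out_dir output directory.
#' @param params a [pipeline_params()].
#' @return the summary list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(sim_config, out_dir, params = pipeline_params()) {
  stopifnot(inherits(sim_config, "simulation_config"),
            inherits(params, "pipeline_params"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  on.exit(writeLines(log, file.path(out_dir, "log.txt")), add = TRUE)
  summary <- list(feature = params$feature)

  log <- stage_msg(log, "stage simulate: generating sessions 1 and 2")
  s1 <- simulate_session1(sim_config)
  s2 <- simulate_session2(sim_config)
  if (params$feature == "theta") {
    s1$epochs <- theta_power(s1$epochs)
    s2$epochs <- theta_power(s2$epochs)
  }
  utils::write.table(s2$behavior, file.path(out_dir, "behavior.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  log <- stage_msg(log, "stage localize: sliding-window decoding per subject")
  subjects <- sort(unique(s1$epochs$metadata$subject))
  wf1 <- lapply(subjects, function(s)
    sliding_window_features(subset_trials(s1$epochs,
                                          s1$epochs$metadata$subject == s),
                            params$window_ms, params$step_ms))
  curves <- lapply(seq_along(subjects), function(i)
    decode_sliding(wf1[[i]], wf1[[i]]$metadata$condition,
                   n_folds = params$n_folds, n_perm = params$n_perm_localizer,
                   seed = child_seed(params$seed, i), C = params$C))
  acc <- do.call(rbind, lapply(curves, `[[`, "accuracy"))
  pmat <- do.call(rbind, lapply(curves, `[[`, "p"))
  start_times <- wf1[[1]]$start_times
  gs <- group_significance(pmat, alpha = params$alpha_localizer,
                           p_clip = 1 / (params$n_perm_localizer + 1))
  win <- select_time_window(start_times, colMeans(acc), apply(acc, 2, stats::sd),
                            gs$mask, sd_mult = params$sd_mult,
                            bridge_ms = params$bridge_ms)
  localizer <- list(start_times = start_times, accuracy = acc, p = pmat,
                    group = gs, window = win)
  saveRDS(localizer, file.path(out_dir, "localizer.rds"))
  summary$decoding <- list(start_times = start_times,
                           group_accuracy = colMeans(acc),
                           group_p = gs$group_p,
                           n_significant = sum(gs$mask))
  summary$selected_window <- list(t_start = win$t_start, t_end = win$t_end)
  # partial summary so an aborted run still documents what it measured
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!length(win$index))
    stop("stage localize: no discriminative window found; later stages not run ",
         "(partial outputs in ", out_dir, ")")
  log <- stage_msg(log, sprintf("selected window %g..%g ms (%d timepoints)",
                                win$t_start, win$t_end, length(win$index)))

  log <- stage_msg(log, "stage transfer: building competition grids")
  grids <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    models <- train_full_models(wf1[[i]], wf1[[i]]$metadata$condition,
                                train_index = win$index, positive = "high",
                                C = params$C)
    wf2 <- sliding_window_features(
      subset_trials(s2$epochs, s2$epochs$metadata$subject == s),
      params$window_ms, params$step_ms)
    grids[[i]] <- apply_grid(models, wf2)
  }
  grid <- structure(list(
    values = do.call(abind3, lapply(grids, `[[`, "values")),
    train_times = grids[[1]]$train_times,
    test_times = grids[[1]]$test_times,
    metadata = do.call(rbind, lapply(grids, `[[`, "metadata"))),
    class = "competition_grid")

  log <- stage_msg(log, "stage drop: scoring competition drops")
  run_branch <- function(ttype) {
    tab <- competition_drop(grid, s2$behavior, trial_type = ttype)
    if (!is.null(params$config_filter))
      tab <- filter_by_configuration(tab, params$config_filter)
    if (params$zscore) tab <- zscore_within_subject(tab)
    tab
  }
  drops <- run_branch("retrieval")
  saveRDS(drops, file.path(out_dir, "drops.rds"))
  summary$n_retained_items <- nrow(drops$items)

  log <- stage_msg(log, "stage cluster: permutation test (retrieval)")
  clus <- cluster_permutation(drops, n_perm = params$n_perm_cluster,
                              threshold = params$cluster_threshold,
                              alpha = params$cluster_alpha,
                              seed = child_seed(params$seed, 21L))
  saveRDS(clus, file.path(out_dir, "clusters.rds"))
  summary$clusters <- clus$clusters
  has_study <- "trial_type" %in% names(grid$metadata) &&
    any(grid$metadata$trial_type == "study")
  if (has_study) {
    log <- stage_msg(log, "stage cluster: study-trial control")
    drops_study <- run_branch("study")
    clus_study <- cluster_permutation(drops_study,
                                      n_perm = params$n_perm_cluster,
                                      threshold = params$cluster_threshold,
                                      alpha = params$cluster_alpha,
                                      seed = child_seed(params$seed, 22L))
    saveRDS(clus_study, file.path(out_dir, "clusters_study.rds"))
    summary$clusters_study <- clus_study$clusters
  }
  if (params$n_boot > 0) {
    log <- stage_msg(log, "stage bootstrap: subject resampling")
    boot <- subject_bootstrap(drops, n_boot = params$n_boot,
                              n_perm = params$n_perm_boot,
                              threshold = params$cluster_threshold,
                              alpha = params$cluster_alpha,
                              seed = child_seed(params$seed, 23L))
    saveRDS(boot, file.path(out_dir, "bootstrap.rds"))
    summary$bootstrap <- list(n_valid = boot$n_valid,
                              max_freq = max(boot$freq))
  }

  log <- stage_msg(log, "stage behavior: configuration analyses")
  configs <- encode_configurations(s2$behavior)
  bp <- behavior_permutation_test(configs, n_perm = params$n_perm_behavior,
                                  n_folds = params$n_folds,
                                  seed = child_seed(params$seed, 31L),
                                  C = params$C)
  summary$behavior <- list(
    accuracy = bp$observed, p = bp$p,
    configuration_counts = as.list(table(configs$configuration)))
  utils::write.table(summarize_rounds(s2$behavior),
                     file.path(out_dir, "round_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log <- stage_msg(log, "pipeline complete")
  invisible(summary)
}

#' Assemble a human-readable report from a completed run
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return character vector of report lines (also written to
#'   `report.txt` in `run_dir`); an incomplete run yields a report
#'   listing the missing stages.
#' @export
make_report <- function(run_dir) {
  sf <- file.path(run_dir, "summary.json")
  lines <- c("Competition-drop analysis report",
             strrep("=", 32))
  expected <- c(summary = "summary.json", localizer = "localizer.rds",
                drops = "drops.rds", clusters = "clusters.rds",
                behavior = "behavior.tsv")
  missing <- names(expected)[!file.exists(file.path(run_dir, expected))]
  if (length(missing)) {
    lines <- c(lines, "", "INCOMPLETE RUN; missing stages:",
               paste(" -", missing))
    writeLines(lines, file.path(run_dir, "report.txt"))
    return(invisible(lines))
  }
  s <- jsonlite::read_json(sf, simplifyVector = TRUE)
  lines <- c(lines, sprintf("features: %s", s$feature), "")
  lines <- c(lines, "Localizer decoding:",
             sprintf("  %d of %d timepoints group-significant",
                     s$decoding$n_significant, length(s$decoding$start_times)),
             sprintf("  peak group accuracy %.3f",
                     max(s$decoding$group_accuracy)))
  if (!is.null(s$selected_window$t_start))
    lines <- c(lines, sprintf("  selected window: %g..%g ms",
                              s$selected_window$t_start, s$selected_window$t_end))
  else
    lines <- c(lines, "  no discriminative window")
  lines <- c(lines, "", sprintf("Retained items: %d", s$n_retained_items),
             "Clusters (retrieval trials):")
  cl <- s$clusters
  if (length(cl) && nrow(as.data.frame(cl)))
    lines <- c(lines, utils::capture.output(print(as.data.frame(cl))))
  else lines <- c(lines, "  none")
  if (!is.null(s$clusters_study)) {
    lines <- c(lines, "Clusters (study-trial control):")
    cs <- as.data.frame(s$clusters_study)
    if (nrow(cs)) lines <- c(lines, utils::capture.output(print(cs)))
    else lines <- c(lines, "  none")
  }
  if (!is.null(s$bootstrap))
    lines <- c(lines, sprintf("Bootstrap: %d valid draws, max inclusion %.2f",
                              s$bootstrap$n_valid, s$bootstrap$max_freq))
  lines <- c(lines, "", "Behavioral prediction:",
             sprintf("  configuration-based accuracy %.3f (p = %.4g)",
                     s$behavior$accuracy, s$behavior$p))
  writeLines(lines, file.path(run_dir, "report.txt"))
  invisible(lines)
}
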