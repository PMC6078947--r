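#' Per-item competition-drop table
#'
#' For every item with at least one correct retrieval round *and* a
#' correct final round, the competition drop at each grid square is the
#' competition probability at the first-correct round minus the
#' probability at the final round. Items never answered correctly, or
#' answered incorrectly in the final round, are excluded (with logged
#' counts).
#'
#' @param grid a [apply_grid()] competition grid whose metadata carries
#'   `subject`, `item`, `round` (and optionally `trial_type`; only
#'   `"retrieval"` trials are used unless `trial_type` says otherwise).
#' @param behavior behavioral table with `subject`, `item`, `round`,
#'   `correct`, `rt_s`, `recalled_s3` covering every grid item.
#' @param trial_type which trial type of the grid to score (the study
#'   control runs the identical path with `"study"`).
#' @return list of class `drop_table`: `drops` (array
#'   `items x train_times x test_times`), `items` (data.frame: `subject`,
#'   `item`, `configuration`, `first_correct`, `recalled_s3`, `rt_drop`),
#'   `train_times`, `test_times`; exclusion counts in attributes
#'   `n_never_correct` and `n_last_incorrect`.
#' @export
competition_drop <- function(grid, behavior, trial_type = "retrieval") {
  stopifnot(inherits(grid, "competition_grid"))
  md <- grid$metadata
  keep <- if ("trial_type" %in% names(md)) md$trial_type == trial_type
          else rep(TRUE, nrow(md))
  n_rounds <- max(behavior$round)
  bkey <- paste(behavior$subject, behavior$item, behavior$round)
  gkey <- paste(md$subject, md$item, md$round)[keep]
  if (!all(gkey %in% bkey))
    stop("grid contains trials with no matching behavior row")
  items <- unique(md[keep, c("subject", "item")])
  rownames(items) <- NULL
  rows <- which(keep)
  drops <- vector("list", nrow(items))
  info <- vector("list", nrow(items))
  n_never <- n_last <- 0L
  for (i in seq_len(nrow(items))) {
    s <- items$subject[i]; it <- items$item[i]
    b <- behavior[behavior$subject == s & behavior$item == it, ]
    b <- b[order(b$round), ]
    if (nrow(b) != n_rounds) stop("behavior must cover every round of every item")
    cfg <- paste(b$correct, collapse = "")
    fc <- which(b$correct == 1)[1]
    if (is.na(fc)) { n_never <- n_never + 1L; next }
    if (b$correct[n_rounds] != 1) { n_last <- n_last + 1L; next }
    tr_first <- rows[md$subject[rows] == s & md$item[rows] == it &
                     md$round[rows] == fc]
    tr_last <- rows[md$subject[rows] == s & md$item[rows] == it &
                    md$round[rows] == n_rounds]
    drops[[i]] <- grid$values[tr_first, , ] - grid$values[tr_last, , ]
    info[[i]] <- data.frame(subject = s, item = it, configuration = cfg,
                            first_correct = fc,
                            recalled_s3 = b$recalled_s3[1],
                            rt_drop = b$rt_s[fc] - b$rt_s[n_rounds])
  }
  kept <- !vapply(drops, is.null, TRUE)
  if (!any(kept)) stop("no item satisfies the retention rule")
  if (n_never + n_last > 0)
    message("excluded ", n_never, " never-correct and ", n_last,
            " final-round-incorrect item(s)")
  arr <- array(NA_real_, c(sum(kept), length(grid$train_times),
                           length(grid$test_times)))
  ki <- which(kept)
  for (j in seq_along(ki)) arr[j, , ] <- drops[[ki[j]]]
  out <- structure(list(drops = arr, items = do.call(rbind, info[kept]),
                        train_times = grid$train_times,
                        test_times = grid$test_times),
                   class = "drop_table")
  attr(out, "n_never_correct") <- n_never
  attr(out, "n_last_incorrect") <- n_last
  out
}

#' @exportS3Method base::print
print.drop_table <- function(x, ...) {
  d <- dim(x$drops)
  cat(sprintf("<drop_table> %d retained items, %d train x %d test squares\n",
              d[1], d[2], d[3]))
  invisible(x)
}

# subset a drop table by item index
subset_drop_table <- function(table, idx) {
  table$drops <- table$drops[idx, , , drop = FALSE]
  table$items <- table$items[idx, , drop = FALSE]
  rownames(table$items) <- NULL
  table
}

#' Restrict a drop table to given response configurations
#'
#' @param table a [competition_drop()] table.
#' @param patterns character vector of 4-bit configuration strings
#'   (e.g. `"0011"`, `"0111"`).
#' @return the restricted `drop_table`; a warning (and an empty table)
#'   if nothing matches.
#' @export
filter_by_configuration <- function(table, patterns) {
  stopifnot(inherits(table, "drop_table"))
  if (!all(grepl("^[01]+$", patterns)))
    stop("patterns must be binary strings such as \"0011\"")
  idx <- which(table$items$configuration %in% patterns)
  if (!length(idx))
    warning("no item matches configuration(s) ", paste(patterns, collapse = ", "))
  subset_drop_table(table, idx)
}

#' Z-score competition drops within subject
#'
#' Per subject and grid square, centers and scales the drop values to
#' mean 0 and SD 1 (n-1 denominator), removing between-subject variance.
#' Subjects with fewer than two retained items, or with zero variance at
#' any square, cannot be scaled and are excluded (with a logged count).
#'
#' @param table a [competition_drop()] table.
#' @return z-scored `drop_table`.
#' @export
zscore_within_subject <- function(table) {
  stopifnot(inherits(table, "drop_table"))
  subj <- table$items$subject
  keep <- rep(TRUE, length(subj))
  for (s in unique(subj)) {
    idx <- which(subj == s)
    if (length(idx) < 2) { keep[idx] <- FALSE; next }
    block <- table$drops[idx, , , drop = FALSE]
    m <- apply(block, c(2, 3), mean)
    sdv <- apply(block, c(2, 3), stats::sd)
    if (any(sdv == 0)) { keep[idx] <- FALSE; next }
    for (j in seq_along(idx))
      table$drops[idx[j], , ] <- (table$drops[idx[j], , ] - m) / sdv
  }
  if (!all(keep))
    message("excluded ", length(unique(subj[!keep])),
            " subject(s) that could not be z-scored")
  subset_drop_table(table, which(keep))
}

#' Reaction-time drop per item
#'
#' RT at the first-correct round minus RT at the final round, under the
#' same retention rule as the competition drop (control analysis).
#'
#' @param behavior behavioral table (`subject`, `item`, `round`,
#'   `correct`, `rt_s`, `recalled_s3`).
#' @return data.frame: `subject`, `item`, `rt_drop`, `recalled_s3`.
#' @export
rt_drop <- function(behavior) {
  n_rounds <- max(behavior$round)
  out <- list()
  for (key in unique(paste(behavior$subject, behavior$item))) {
    b <- behavior[paste(behavior$subject, behavior$item) == key, ]
    b <- b[order(b$round), ]
    fc <- which(b$correct == 1)[1]
    if (is.na(fc) || b$correct[n_rounds] != 1) next
    if (any(is.na(b$rt_s[c(fc, n_rounds)]))) next
    out[[key]] <- data.frame(subject = b$subject[1], item = b$item[1],
                             rt_drop = b$rt_s[fc] - b$rt_s[n_rounds],
                             recalled_s3 = b$recalled_s3[1])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
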