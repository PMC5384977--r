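#' Default eRT-referenced analysis windows
#'
#' The four windows of mean rectified EMG taken relative to each trial's
#' earliest reaction time: 0-10, 10-20, 20-30 and 50-100 ms. Windows are
#' half-open `[start, end)` so adjacent windows never double-count a sample.
#'
#' @return data.frame with columns start_ms, end_ms, label.
#' @export
default_windows <- function() {
  data.frame(start_ms = c(0, 10, 20, 50), end_ms = c(10, 20, 30, 100),
             label = c("0-10", "10-20", "20-30", "50-100"),
             stringsAsFactors = FALSE)
}

validate_windows <- function(windows) {
  stopifnot(is.data.frame(windows),
            all(c("start_ms", "end_ms", "label") %in% names(windows)))
  if (any(windows$start_ms >= windows$end_ms)) {
    stop("window start must be < end")
  }
  windows
}

#' Window means of rectified EMG for one trial
#'
#' For each analysis window, each muscle's value is the mean of the raw
#' rectified signal over samples with time in `[ert + start, ert + end)` ms
#' after the stimulus. These are the nonnegative activation vectors that feed
#' both the condition matrices and the similarity analysis.
#'
#' @param trial An [emg_trial].
#' @param ert_ms The trial's earliest reaction time (ms after stimulus).
#' @param windows Window table as from [default_windows()].
#' @return Numeric matrix, windows x muscles, rownames = window labels.
#' @export
window_means <- function(trial, ert_ms, windows = default_windows()) {
  stopifnot(inherits(trial, "emg_trial"))
  windows <- validate_windows(windows)
  if (is.na(ert_ms)) stop("ert missing")
  fs <- trial$sample_rate_hz
  t_ms <- (seq_len(ncol(trial$signal)) - 1) * 1000 / fs - trial$stimulus_time_ms
  if (max(t_ms) < ert_ms + max(windows$end_ms) - 1000 / fs) {
    stop("signal too short for window ", windows$label[which.max(windows$end_ms)])
  }
  rect <- abs(trial$signal)
  out <- matrix(NA_real_, nrow(windows), length(trial$muscles),
                dimnames = list(windows$label, trial$muscles))
  for (w in seq_len(nrow(windows))) {
    idx <- which(t_ms >= ert_ms + windows$start_ms[w] &
                   t_ms < ert_ms + windows$end_ms[w])
    if (!length(idx)) stop("empty window ", windows$label[w])
    out[w, ] <- rowMeans(rect[, idx, drop = FALSE])
  }
  out
}

#' Extract window features for every trial with a detected eRT
#'
#' Trials whose eRT is missing are skipped with a warning; they take no
#' further part in the analysis.
#'
#' @param set A [trial_set].
#' @param onsets An `onset_table` from [detect_onsets()].
#' @param windows Window table as from [default_windows()].
#' @return An object of class `window_features`: a data.table with the trial
#'   key columns, `ert_ms`, `window`, and one column per muscle (mean
#'   rectified EMG, amplitude units). Attributes `muscles` and `windows`.
#' @export
extract_features <- function(set, onsets, windows = default_windows()) {
  stopifnot(inherits(set, "trial_set"), inherits(onsets, "onset_table"))
  windows <- validate_windows(windows)
  ert <- onsets$trials
  rows <- list()
  n_skipped <- 0L
  for (tr in set$trials) {
    e <- ert[ert$subject_id == tr$subject_id & ert$task_id == tr$task_id &
               ert$cue == tr$cue & ert$trial_index == tr$trial_index, ]
    if (nrow(e) != 1) stop("no onset result for trial ", trial_key(tr))
    if (is.na(e$ert_ms)) { n_skipped <- n_skipped + 1L; next }
    wm <- window_means(tr, e$ert_ms, windows)
    rows[[length(rows) + 1L]] <- cbind(
      data.table::data.table(subject_id = tr$subject_id, task_id = tr$task_id,
                             cue = tr$cue, trial_index = tr$trial_index,
                             ert_ms = e$ert_ms, window = rownames(wm)),
      data.table::as.data.table(wm)
    )
  }
  if (n_skipped > 0) {
    warning(n_skipped, " trial(s) without detected eRT excluded from features")
  }
  out <- data.table::rbindlist(rows)
  muscles <- if (length(set$trials)) set$trials[[1]]$muscles else character()
  structure(out, muscles = muscles, windows = windows,
            class = c("window_features", class(out)))
}

#' Exclude slow loud trials and randomly matched quiet trials
#'
#' Within one subject, removes loud-cue trials whose eRT exceeds `cutoff_ms`
#' and an equal number of quiet-cue trials selected uniformly at random
#' (pooled across tasks) using `seed`. Trials with missing eRT are dropped
#' first with a warning. If the two cues end up with unequal trial counts
#' (possible only when missing-eRT drops were asymmetric), the larger side is
#' randomly trimmed so the loud and quiet matrices always have equal n.
#'
#' @param trials data.frame/data.table of one subject's trials with columns
#'   subject_id, task_id, cue, trial_index, ert_ms.
#' @param cutoff_ms Loud eRT exclusion cutoff, default 100.
#' @param seed Seed for the random quiet selection.
#' @return List: `kept` (data.table of retained trial keys + cue + ert_ms),
#'   `excluded` (data.table with a `reason` column), `n_excluded`
#'   (named counts per cue), `seed`, and `loud_random_trim` (TRUE if loud
#'   trials had to be randomly trimmed for balance).
#' @export
exclude_and_match <- function(trials, cutoff_ms = 100, seed = 1) {
  trials <- data.table::as.data.table(trials)
  stopifnot(all(c("subject_id", "task_id", "cue", "trial_index", "ert_ms")
                %in% names(trials)))
  if (length(unique(trials$subject_id)) > 1) {
    stop("exclude_and_match operates on a single subject")
  }
  miss <- is.na(trials$ert_ms)
  excluded <- list()
  if (any(miss)) {
    warning(sum(miss), " trial(s) without eRT dropped before matching")
    excluded[[length(excluded) + 1L]] <- cbind(trials[miss], reason = "no_ert")
    trials <- trials[!miss]
  }
  is_loud <- trials$cue == "loud"
  slow_loud <- is_loud & trials$ert_ms > cutoff_ms
  n_excl <- sum(slow_loud)
  quiet_idx <- which(!is_loud)
  if (n_excl > length(quiet_idx)) {
    stop("more loud exclusions (", n_excl, ") than available quiet trials (",
         length(quiet_idx), ")")
  }
  if (n_excl > 0) {
    excluded[[length(excluded) + 1L]] <-
      cbind(trials[which(slow_loud)], reason = "loud_ert_over_cutoff")
  }
  drop <- slow_loud
  if (n_excl > 0) {
    q_drop <- with_seed(split_seed(seed, "quiet_match"),
                        sample(quiet_idx, n_excl))
    drop[q_drop] <- TRUE
    excluded[[length(excluded) + 1L]] <-
      cbind(trials[q_drop], reason = "quiet_random_match")
  }
  kept <- trials[!drop]
  loud_random_trim <- FALSE
  n_l <- sum(kept$cue == "loud"); n_q <- sum(kept$cue == "quiet")
  if (n_l != n_q) {               # only reachable after asymmetric eRT losses
    big <- if (n_l > n_q) "loud" else "quiet"
    extra <- abs(n_l - n_q)
    pool <- which(kept$cue == big)
    trim <- with_seed(split_seed(seed, "balance"), sample(pool, extra))
    excluded[[length(excluded) + 1L]] <-
      cbind(kept[trim], reason = "random_balance_trim")
    kept <- kept[-trim]
    if (big == "loud") loud_random_trim <- TRUE
  }
  excl_dt <- if (length(excluded)) data.table::rbindlist(excluded)
             else cbind(trials[0], reason = character())
  list(
    kept = kept, excluded = excl_dt,
    n_excluded = c(loud = sum(excl_dt$cue == "loud"),
                   quiet = sum(excl_dt$cue == "quiet")),
    seed = seed, loud_random_trim = loud_random_trim
  )
}

#' Assemble a per-condition muscle-activity matrix
#'
#' Stacks the window-mean activation vectors of the retained trials of one
#' subject, cue and window into an n x muscles matrix, rows in deterministic
#' (task, trial_index) order.
#'
#' @param features A `window_features` table from [extract_features()].
#' @param kept data.table of retained trial keys (as from
#'   [exclude_and_match()]'s `kept`).
#' @param subject,cue,window Selection.
#' @return Numeric matrix with attributes subject, cue, window, zscored
#'   (FALSE) and trial key data.frame `trial_keys`.
#' @export
build_condition_matrix <- function(features, kept, subject, cue, window) {
  muscles <- attr(features, "muscles")
  sel <- features$subject_id == subject & features$cue == cue &
    features$window == window
  ft <- features[which(sel), ]
  k <- data.table::as.data.table(kept)
  ksel <- k$cue == cue
  k <- k[which(ksel), c("task_id", "trial_index")]
  ft <- merge(ft, k, by = c("task_id", "trial_index"))
  if (nrow(ft) == 0) stop("no included trials for ", subject, "/", cue, "/", window)
  ord <- order(ft$task_id, ft$trial_index)
  ft <- ft[ord, ]
  m <- as.matrix(ft[, muscles, with = FALSE])
  rownames(m) <- paste(ft$task_id, ft$trial_index, sep = ".")
  structure(m, subject = subject, cue = cue, window = window, zscored = FALSE,
            trial_keys = data.frame(task_id = ft$task_id,
                                    trial_index = ft$trial_index))
}

#' Z-score the columns of a condition matrix
#'
#' Standardizes each muscle column to zero mean and unit SD (n-1
#' denominator). Zero-variance columns are flagged degenerate and set to
#' all-zero rather than producing NaNs, keeping the eigen-analysis
#' well-defined; the flag is carried in the `degenerate` attribute.
#'
#' @param m Condition matrix from [build_condition_matrix()] (n >= 2 rows).
#' @return The standardized matrix, with `zscored = TRUE` and a logical
#'   `degenerate` attribute per column.
#' @export
zscore_columns <- function(m) {
  if (nrow(m) < 2) stop("need at least 2 rows to z-score")
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  degen <- sdv == 0
  z <- sweep(m, 2, mu, "-")
  z[, !degen] <- sweep(z[, !degen, drop = FALSE], 2, sdv[!degen], "/")
  z[, degen] <- 0
  attrs <- attributes(m)
  for (a in setdiff(names(attrs), c("dim", "dimnames"))) attr(z, a) <- attrs[[a]]
  attr(z, "zscored") <- TRUE
  attr(z, "degenerate") <- degen
  z
}
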