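#' Detect per-muscle reaction times in one trial
#'
#' The EMG is rectified (absolute value) and, per muscle, a threshold is set
#' at `k_sd` SDs above the mean of the rectified signal over the
#' `baseline_ms` window immediately preceding the stimulus (half-open
#' `[-baseline_ms, 0)` ms, n-1 SD). The reaction time is the first time
#' after the stimulus at which the processed signal strictly exceeds the
#' threshold; the trial's earliest reaction time (eRT) is the minimum over
#' muscles of the detected reaction times.
#'
#' Two optional robustness parameters stand in for the manual inspection of
#' automated markings that is impractical in a scripted pipeline: a centered
#' moving-average smoothing of the rectified signal (`smooth_ms`) and a
#' debounce (`min_above_ms`) requiring the signal to stay above threshold for
#' a minimum duration at the crossing. Both default to 0 (the plain
#' single-sample rule); baseline statistics are always computed on the same
#' processed signal that is thresholded.
#'
#' @param trial An [emg_trial].
#' @param baseline_ms Baseline window length before the stimulus (ms).
#' @param k_sd Threshold multiplier (threshold = mean + k_sd * SD).
#' @param search_limit_ms Latest allowed crossing time after the stimulus.
#' @param smooth_ms Centered moving-average window applied to the rectified
#'   signal before thresholding; 0 disables smoothing.
#' @param min_above_ms Minimum supra-threshold duration for a crossing to
#'   count; 0 accepts single-sample crossings.
#' @return An object of class `onset_result`: a list with `per_muscle`
#'   (data.table: muscle, baseline_mean, baseline_sd, threshold, rt_ms),
#'   `ert_ms` (NA if no muscle crossed), the trial key fields, and the
#'   detection parameters.
#' @export
detect_rt <- function(trial, baseline_ms = 200, k_sd = 3,
                      search_limit_ms = 500, smooth_ms = 0, min_above_ms = 0) {
  stopifnot(inherits(trial, "emg_trial"))
  if (search_limit_ms <= 0) stop("zero-length search window")
  fs <- trial$sample_rate_hz
  dt_ms <- 1000 / fs
  n <- ncol(trial$signal)
  nm <- length(trial$muscles)
  t_ms <- (seq_len(n) - 1) * dt_ms - trial$stimulus_time_ms  # 0 = stimulus
  base_idx <- which(t_ms >= -baseline_ms & t_ms < 0)
  if (!length(base_idx) || min(t_ms) > -baseline_ms + dt_ms / 2) {
    stop("baseline window not covered by signal")
  }
  post_idx <- which(t_ms > 0)
  if (!length(post_idx)) stop("no post-stimulus samples")
  w <- 0L
  if (smooth_ms > 0) {
    w <- as.integer(round(smooth_ms / dt_ms))
    if (w %% 2L == 0L) w <- w + 1L
  }
  d_samp <- max(1L, as.integer(ceiling(min_above_ms / dt_ms)))
  p_lo <- post_idx[1]
  max_start <- sum(t_ms[post_idx] <= search_limit_ms)
  res <- .cpp_detect_kernel(trial$signal, base_idx[1],
                            base_idx[length(base_idx)], p_lo,
                            k_sd, w, d_samp, max_start)
  bmean <- res$baseline_mean
  bsd <- res$baseline_sd
  thr <- res$threshold
  rt_ms <- ifelse(res$rt_idx > 0, t_ms[pmax(res$rt_idx, 1L)], NA_real_)
  structure(list(
    subject_id = trial$subject_id, task_id = trial$task_id, cue = trial$cue,
    trial_index = trial$trial_index,
    per_muscle = data.table::data.table(
      muscle = trial$muscles, baseline_mean = bmean, baseline_sd = bsd,
      threshold = thr, rt_ms = rt_ms
    ),
    ert_ms = if (all(is.na(rt_ms))) NA_real_ else min(rt_ms, na.rm = TRUE),
    params = list(baseline_ms = baseline_ms, k_sd = k_sd,
                  search_limit_ms = search_limit_ms, smooth_ms = smooth_ms,
                  min_above_ms = min_above_ms),
    overrides = list()
  ), class = "onset_result")
}

#' @export
print.onset_result <- function(x, ...) {
  cat("<onset_result>", x$subject_id, "task", x$task_id, x$cue,
      "trial", x$trial_index, "- eRT:",
      if (is.na(x$ert_ms)) "none" else sprintf("%.2f ms", x$ert_ms), "\n")
  invisible(x)
}

#' Detect reaction times for every trial in a set
#'
#' Runs [detect_rt()] over all trials and assembles tabular results.
#'
#' @param set A [trial_set].
#' @param ... Passed to [detect_rt()].
#' @return An object of class `onset_table`: list with `muscle_rt`
#'   (data.table: subject_id, task_id, cue, trial_index, muscle,
#'   baseline_mean, baseline_sd, threshold, rt_ms, overridden) and `trials`
#'   (data.table: subject_id, task_id, cue, trial_index, ert_ms).
#' @export
detect_onsets <- function(set, ...) {
  stopifnot(inherits(set, "trial_set"))
  res <- lapply(set$trials, detect_rt, ...)
  nm <- if (length(res)) nrow(res[[1]]$per_muscle) else 0L
  sid <- vapply(res, `[[`, character(1), "subject_id")
  tid <- vapply(res, `[[`, integer(1), "task_id")
  cue <- vapply(res, `[[`, character(1), "cue")
  tix <- vapply(res, `[[`, integer(1), "trial_index")
  muscle_rt <- data.table::data.table(
    subject_id = rep(sid, each = nm), task_id = rep(tid, each = nm),
    cue = rep(cue, each = nm), trial_index = rep(tix, each = nm),
    muscle = unlist(lapply(res, function(r) r$per_muscle$muscle), use.names = FALSE),
    baseline_mean = unlist(lapply(res, function(r) r$per_muscle$baseline_mean), use.names = FALSE),
    baseline_sd = unlist(lapply(res, function(r) r$per_muscle$baseline_sd), use.names = FALSE),
    threshold = unlist(lapply(res, function(r) r$per_muscle$threshold), use.names = FALSE),
    rt_ms = unlist(lapply(res, function(r) r$per_muscle$rt_ms), use.names = FALSE),
    overridden = FALSE
  )
  trials <- data.table::data.table(
    subject_id = sid, task_id = tid, cue = cue, trial_index = tix,
    ert_ms = vapply(res, `[[`, numeric(1), "ert_ms")
  )
  structure(list(muscle_rt = muscle_rt, trials = trials),
            class = "onset_table")
}

#' Apply manual reaction-time overrides
#'
#' Replaces listed per-muscle reaction times (the scripted analogue of
#' correcting inaccurately placed automated markings) and recomputes the
#' affected trials' earliest reaction times. Provenance is kept in the
#' `overridden` column.
#'
#' @param onsets An `onset_table` from [detect_onsets()].
#' @param overrides data.frame with columns subject_id, task_id, cue,
#'   trial_index, muscle, rt_ms (NA removes a detection).
#' @return The modified `onset_table`.
#' @export
apply_overrides <- function(onsets, overrides) {
  stopifnot(inherits(onsets, "onset_table"))
  if (is.null(overrides) || nrow(overrides) == 0) return(onsets)
  mr <- data.table::copy(onsets$muscle_rt)
  for (i in seq_len(nrow(overrides))) {
    o <- overrides[i, ]
    sel <- mr$subject_id == o$subject_id & mr$task_id == o$task_id &
      mr$cue == o$cue & mr$trial_index == o$trial_index & mr$muscle == o$muscle
    if (!any(sel)) {
      stop("override ", i, ": unknown trial/muscle ",
           paste(o$subject_id, o$task_id, o$cue, o$trial_index, o$muscle))
    }
    data.table::set(mr, which(sel), "rt_ms", as.numeric(o$rt_ms))
    data.table::set(mr, which(sel), "overridden", TRUE)
  }
  trials <- mr[, list(ert_ms = if (all(is.na(rt_ms))) NA_real_
                      else min(rt_ms, na.rm = TRUE)),
               by = c("subject_id", "task_id", "cue", "trial_index")]
  structure(list(muscle_rt = mr, trials = trials), class = "onset_table")
}

#' Compare earliest reaction times between cue conditions
#'
#' Reports a Lilliefors-corrected Kolmogorov-Smirnov normality assessment for
#' each sample, a two-sided Wilcoxon rank-sum p-value, per-condition
#' mean +/- SD and the mean difference (quiet - loud). The rank-sum test is
#' used because eRT samples are typically non-normal.
#'
#' @param erts_quiet,erts_loud Numeric vectors of per-trial eRTs (ms).
#' @return An object of class `rt_comparison` (list).
#' @export
compare_reaction_times <- function(erts_quiet, erts_loud) {
  erts_quiet <- erts_quiet[!is.na(erts_quiet)]
  erts_loud <- erts_loud[!is.na(erts_loud)]
  if (!length(erts_quiet) || !length(erts_loud)) stop("empty eRT sample")
  norm_p <- function(x) {
    if (length(x) < 5 || sd(x) == 0) return(NA_real_)
    nortest::lillie.test(x)$p.value
  }
  w <- suppressWarnings(wilcox.test(erts_quiet, erts_loud,
                                    alternative = "two.sided"))
  structure(list(
    n_quiet = length(erts_quiet), n_loud = length(erts_loud),
    mean_quiet = mean(erts_quiet), sd_quiet = sd(erts_quiet),
    mean_loud = mean(erts_loud), sd_loud = sd(erts_loud),
    mean_difference = mean(erts_quiet) - mean(erts_loud),
    normality_p_quiet = norm_p(erts_quiet),
    normality_p_loud = norm_p(erts_loud),
    rank_sum_p = w$p.value
  ), class = "rt_comparison")
}

#' @export
print.rt_comparison <- function(x, ...) {
  cat(sprintf("eRT quiet: %.1f +/- %.1f ms (n=%d)\n",
              x$mean_quiet, x$sd_quiet, x$n_quiet))
  cat(sprintf("eRT loud:  %.1f +/- %.1f ms (n=%d)\n",
              x$mean_loud, x$sd_loud, x$n_loud))
  cat(sprintf("difference %.1f ms; rank-sum p = %.3g\n",
              x$mean_difference, x$rank_sum_p))
  invisible(x)
}
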