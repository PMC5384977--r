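#' Cosine similarity of two activation vectors
#'
#' `x . y / (|x| |y|)`: the cosine of the angle between the vectors -- 1 if
#' they point in the same direction, 0 if orthogonal. For nonnegative
#' activation vectors the value lies in \[0, 1\], and it is invariant to
#' positive rescaling of either vector.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Scalar similarity; `NA` (with a warning) if either vector has
#'   zero magnitude, for which the measure is undefined.
#' @export
cosine_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    warning("zero-magnitude vector: similarity undefined")
    return(NA_real_)
  }
  sum(x * y) / (nx * ny)
}

#' The four trial-pair similarity comparison sets
#'
#' From the (non-z-scored) window-mean activation vectors of the retained
#' trials, computes pairwise cosine similarities pooled across tasks and
#' subjects for four comparison sets:
#' \describe{
#'   \item{same_task_quiet}{unordered pairs of distinct quiet-cue trials of
#'     the same task,}
#'   \item{same_task_loud}{the same for loud-cue trials,}
#'   \item{diff_task_quiet}{unordered pairs of quiet-cue trials from two
#'     different tasks (within subject),}
#'   \item{same_task_quiet_loud}{all cross-cue pairs within a task (one
#'     quiet, one loud trial).}
#' }
#' Pairs are unordered and counted once; self-pairs are excluded. Trials of
#' different subjects are never paired (electrode placement differs between
#' subjects). Trials with all-zero activation vectors contribute no pairs
#' and are counted in `skipped_zero`.
#'
#' @param features `window_features` from [extract_features()] (raw window
#'   means -- cosine similarity is per-trial scale-invariant, so z-scoring
#'   is neither needed nor wanted here).
#' @param kept data.table of retained trial keys with columns subject_id,
#'   task_id, cue, trial_index (post-exclusion trials from
#'   [exclude_and_match()], combined across subjects).
#' @param window Window label to analyze.
#' @return Named list of four `similarity_distribution` objects (fields:
#'   label, window, values, n_pairs, skipped_zero).
#' @export
similarity_sets <- function(features, kept, window) {
  muscles <- attr(features, "muscles")
  kept <- data.table::as.data.table(kept)
  wsel <- features$window == window
  ft <- features[which(wsel), ]
  ft <- merge(ft, kept[, c("subject_id", "task_id", "cue", "trial_index")],
              by = c("subject_id", "task_id", "cue", "trial_index"))
  vals <- list(same_task_quiet = list(), same_task_loud = list(),
               diff_task_quiet = list(), same_task_quiet_loud = list())
  skipped <- 0L
  for (sid in unique(ft$subject_id)) {
    sub <- ft[ft$subject_id == sid, ]
    X <- as.matrix(sub[, muscles, with = FALSE])
    norms <- sqrt(rowSums(X^2))
    nz <- norms > 0
    skipped <- skipped + sum(!nz)
    if (sum(nz) < 2) next
    X <- X[nz, , drop = FALSE] / norms[nz]
    task <- sub$task_id[nz]; cue <- sub$cue[nz]
    G <- tcrossprod(X)
    n <- nrow(X)
    pair_upper <- function(keep_row) {
      idx <- which(upper.tri(G) & keep_row)
      G[idx]
    }
    same_task <- outer(task, task, "==")
    both_quiet <- outer(cue == "quiet", cue == "quiet", "&")
    both_loud <- outer(cue == "loud", cue == "loud", "&")
    cross_cue <- outer(cue == "quiet", cue == "loud", "&")  # ordered q x l
    vals$same_task_quiet[[sid]] <- pair_upper(same_task & both_quiet)
    vals$same_task_loud[[sid]] <- pair_upper(same_task & both_loud)
    vals$diff_task_quiet[[sid]] <- pair_upper(!same_task & both_quiet)
    vals$same_task_quiet_loud[[sid]] <- G[same_task & cross_cue]
  }
  labels <- c(same_task_quiet = "same-task quiet-quiet",
              same_task_loud = "same-task loud-loud",
              diff_task_quiet = "different-task quiet-quiet",
              same_task_quiet_loud = "same-task quiet-loud")
  out <- lapply(names(vals), function(k) {
    v <- unlist(vals[[k]], use.names = FALSE) %||% numeric()
    structure(list(label = labels[[k]], window = window, values = v,
                   n_pairs = length(v), skipped_zero = skipped),
              class = "similarity_distribution")
  })
  names(out) <- names(vals)
  out
}

#' @export
print.similarity_distribution <- function(x, ...) {
  cat(sprintf("<similarity_distribution> %s, window %s: %d pairs, mean %.3f\n",
              x$label, x$window, x$n_pairs,
              if (x$n_pairs) mean(x$values) else NA))
  invisible(x)
}

#' Summarize similarity distributions
#'
#' Per comparison set: mean similarity and the fraction of values above the
#' report cutoff (default 0.8), plus Welch two-sample t-tests of each other
#' set against the same-task quiet-quiet reference, and of same-task
#' loud-loud against same-task quiet-loud. Overlapping pairs make the
#' similarity values statistically dependent; the t-tests ignore this, which
#' is the conventional treatment for such pooled pairwise measures and
#' should be read descriptively.
#'
#' @param sets Named list from [similarity_sets()].
#' @param cutoff Report cutoff for the distribution fraction, default 0.8.
#' @return List with `table` (data.frame: set, label, n_pairs, mean,
#'   frac_above_cutoff, p_vs_same_task_quiet) and `loud_vs_crosscue_p`.
#' @export
summarize_similarity <- function(sets, cutoff = 0.8) {
  stopifnot(all(c("same_task_quiet", "same_task_loud", "diff_task_quiet",
                  "same_task_quiet_loud") %in% names(sets)))
  ref <- sets$same_task_quiet$values
  if (!length(ref)) stop("empty reference similarity distribution")
  rows <- lapply(names(sets), function(k) {
    v <- sets[[k]]$values
    if (!length(v)) stop("empty similarity distribution: ", k)
    p <- if (k == "same_task_quiet") NA_real_ else {
      if (sd(v) == 0 && sd(ref) == 0) NA_real_
      else t.test(v, ref)$p.value
    }
    data.frame(set = k, label = sets[[k]]$label, n_pairs = length(v),
               mean = mean(v), frac_above_cutoff = mean(v > cutoff),
               p_vs_same_task_quiet = p, stringsAsFactors = FALSE)
  })
  ll <- sets$same_task_loud$values; ql <- sets$same_task_quiet_loud$values
  lvc <- if (sd(ll) == 0 && sd(ql) == 0) NA_real_ else t.test(ll, ql)$p.value
  list(table = do.call(rbind, rows), loud_vs_crosscue_p = lvc,
       cutoff = cutoff, window = sets$same_task_quiet$window)
}

#' Empirical cumulative distribution export for plotting
#'
#' @param dist A `similarity_distribution`.
#' @return data.frame with sorted `value` and cumulative probability `p`.
#' @export
similarity_ecdf <- function(dist) {
  v <- sort(dist$values)
  data.frame(value = v, p = seq_along(v) / length(v))
}
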