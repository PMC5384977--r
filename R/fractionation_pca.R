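#' Covariance matrix of a z-scored condition matrix
#'
#' Sample covariance (n-1 denominator) between muscle columns. For z-scored
#' input the diagonal is 1 for every non-degenerate column, so the total
#' variance equals the number of non-degenerate muscles.
#'
#' @param m A z-scored matrix from [zscore_columns()], n >= 2 rows.
#' @return Symmetric muscles x muscles covariance matrix.
#' @export
covariance_matrix <- function(m) {
  if (!isTRUE(attr(m, "zscored"))) stop("matrix must be z-scored first")
  if (nrow(m) < 2) stop("need at least 2 rows")
  cv <- stats::cov(m)
  attr(cv, "degenerate") <- attr(m, "degenerate")
  cv
}

#' CPVE curve from a covariance matrix
#'
#' Eigendecomposition of the (symmetric) covariance matrix gives the
#' principal components; eigenvalues are sorted in descending order,
#' expressed as percent of their sum, and cumulated into the cumulative
#' percentage of variance explained (CPVE). A slowly rising curve indicates
#' highly fractionated (high-dimensional) muscle use; a curve reaching 100
#' with few components indicates stereotyped, low-dimensional activation.
#'
#' Tiny negative eigenvalues (magnitude below `1e-10 * trace`, numerical
#' round-off) are clipped to zero; larger negative eigenvalues signal a
#' non-PSD input and raise an error.
#'
#' @param cv Symmetric covariance matrix.
#' @return Object of class `cpve_curve`: numeric vector of cumulative
#'   percentages, one per component, nondecreasing and ending at 100.
#' @export
cpve_from_covariance <- function(cv) {
  stopifnot(is.matrix(cv), nrow(cv) == ncol(cv))
  if (max(abs(cv - t(cv))) > 1e-8 * max(1, max(abs(cv)))) {
    stop("covariance matrix must be symmetric")
  }
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  tr <- sum(diag(cv))
  tol <- 1e-10 * max(tr, 1)
  if (any(ev < -tol)) stop("covariance matrix is not positive semi-definite")
  ev[ev < 0] <- 0
  total <- sum(ev)
  if (total <= 0) stop("zero total variance: all-zero covariance matrix")
  ev <- sort(ev, decreasing = TRUE)
  structure(cumsum(ev) / total * 100, class = "cpve_curve")
}

#' @export
print.cpve_curve <- function(x, ...) {
  cat("<cpve_curve>", paste(sprintf("%.1f", unclass(x)), collapse = " "), "\n")
  invisible(x)
}

#' Per-condition CPVE curves averaged over repeated random exclusions
#'
#' For one subject and window: repeats the exclude/match -> stack -> z-score
#' -> covariance -> CPVE chain `repeats` times with different random
#' selections of matched quiet trials, and averages the resulting CPVE
#' curves per condition. The loud-cue exclusions are deterministic (eRT >
#' cutoff), so the loud curve must be identical across repeats; this is
#' verified unless loud trials had to be randomly trimmed for balance.
#'
#' @param features `window_features` from [extract_features()].
#' @param subject Subject id.
#' @param window Window label.
#' @param cutoff_ms Loud eRT exclusion cutoff (ms), default 100.
#' @param repeats Number of random-exclusion repeats, default 100.
#' @param base_seed Seed; repeat r uses a deterministic function of
#'   (base_seed, subject, r).
#' @return List with `quiet` and `loud` mean `cpve_curve`s, `quiet_sd`
#'   (across-repeat SD per component), `repeats`, `n_trials` (matched n per
#'   condition in the first repeat), and `n_excluded`.
#' @export
averaged_cpve <- function(features, subject, window, cutoff_ms = 100,
                          repeats = 100, base_seed = 1) {
  stopifnot(repeats >= 1)
  sel <- features$subject_id == subject & features$window == window
  sub <- features[which(sel), ]
  if (nrow(sub) == 0) stop("no features for subject ", subject, " window ", window)
  trials <- unique(sub[, c("subject_id", "task_id", "cue", "trial_index", "ert_ms")])
  nc <- NULL
  acc <- list(quiet = NULL, loud = NULL)
  loud_ref <- NULL
  n_trials <- NULL; n_excluded <- NULL
  for (r in seq_len(repeats)) {
    em <- exclude_and_match(trials, cutoff_ms = cutoff_ms,
                            seed = split_seed(base_seed, subject, r))
    curves <- lapply(c(quiet = "quiet", loud = "loud"), function(cue) {
      m <- build_condition_matrix(features, em$kept, subject, cue, window)
      cpve_from_covariance(covariance_matrix(zscore_columns(m)))
    })
    if (is.null(nc)) {
      nc <- length(curves$quiet)
      acc$quiet <- matrix(NA_real_, repeats, nc)
      acc$loud <- matrix(NA_real_, repeats, nc)
      n_trials <- c(quiet = sum(em$kept$cue == "quiet"),
                    loud = sum(em$kept$cue == "loud"))
      n_excluded <- em$n_excluded
    }
    acc$quiet[r, ] <- unclass(curves$quiet)
    acc$loud[r, ] <- unclass(curves$loud)
    if (!em$loud_random_trim) {
      if (is.null(loud_ref)) {
        loud_ref <- unclass(curves$loud)
      } else if (max(abs(unclass(curves$loud) - loud_ref)) > 1e-9) {
        stop("internal error: loud CPVE varied across repeats without random trimming")
      }
    }
  }
  list(
    quiet = structure(colMeans(acc$quiet), class = "cpve_curve"),
    loud = structure(colMeans(acc$loud), class = "cpve_curve"),
    quiet_sd = apply(acc$quiet, 2, sd),
    repeats = repeats, n_trials = n_trials, n_excluded = n_excluded
  )
}
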