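#' Enumerate within-subject condition-swap assignments
#'
#' Every subset of subjects whose loud/quiet curves are swapped appears
#' exactly once: 2^S assignments for S subjects, the first row being the
#' identity (no swaps). For S > 20 exhaustive enumeration is impractical and
#' 2^20 random assignments are drawn instead (identity forced in first),
#' a documented deviation from exhaustiveness.
#'
#' @param S Number of subjects.
#' @param seed Seed used only in the S > 20 sampling fallback.
#' @return Integer 0/1 matrix, assignments x subjects; 1 = swapped.
#' @export
enumerate_swaps <- function(S, seed = 1) {
  stopifnot(S >= 1)
  if (S <= 20) {
    m <- as.matrix(expand.grid(rep(list(0:1), S), KEEP.OUT.ATTRS = FALSE))
  } else {
    n <- 2^20
    m <- with_seed(split_seed(seed, "swaps"),
                   matrix(sample(0:1, n * S, replace = TRUE), n, S))
    m[1, ] <- 0L
  }
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Surrogate difference-of-means CPVE curves under condition relabeling
#'
#' For each swap assignment, the per-subject loud/quiet curves are exchanged
#' according to the assignment, condition means over subjects are taken, and
#' the difference (relabeled-loud mean minus relabeled-quiet mean) is stored.
#' Under exhaustive enumeration the set is symmetric: each assignment's
#' complement produces the negated curve, and the identity row reproduces
#' the observed difference.
#'
#' @param loud,quiet Matrices, subjects x components, of per-subject mean
#'   CPVE curves (same subject order in both).
#' @param swaps Swap matrix from [enumerate_swaps()]; default enumerates
#'   exhaustively for `nrow(loud)` subjects.
#' @return Object of class `surrogate_set`: matrix (assignments x
#'   components) of difference curves, with the swap matrix in attribute
#'   `swaps`. Row 1 is the observed (identity) difference.
#' @export
surrogate_differences <- function(loud, quiet, swaps = NULL) {
  loud <- as.matrix(loud); quiet <- as.matrix(quiet)
  if (!all(dim(loud) == dim(quiet))) stop("mismatched subjects between conditions")
  S <- nrow(loud)
  if (is.null(swaps)) swaps <- enumerate_swaps(S)
  stopifnot(ncol(swaps) == S)
  # Swapping subject s negates its contribution to the difference of means:
  # diff = (1/S) * sum_s sign_s * (loud_s - quiet_s), sign_s = +1 unswapped.
  D <- (loud - quiet) / S
  signs <- 1 - 2 * swaps
  surr <- signs %*% D
  structure(surr, swaps = swaps, class = c("surrogate_set", class(surr)))
}

# Number of surrogate rows with >= 1 component strictly outside the rank-n
# thresholds (n-th smallest, n-th largest per component).
count_detections <- function(surr, n) {
  M <- nrow(surr)
  sorted <- apply(surr, 2, sort)
  lower <- sorted[n, ]
  upper <- sorted[M - n + 1, ]
  det <- sweep(surr, 2, lower, "<") | sweep(surr, 2, upper, ">")
  sum(rowSums(det) > 0)
}

#' Calibrate the per-component rank threshold to a family-wise bound
#'
#' For a candidate rank n, the per-component thresholds are the n-th
#' smallest and n-th largest surrogate values (1-based); a surrogate row is
#' a detection if any component lies strictly outside its thresholds. The
#' achieved detection count is nondecreasing in n (thresholds are nested),
#' so the largest n whose count stays at or below `target_count` is found by
#' binary search; monotonicity between the probed points is asserted.
#'
#' With 1,024 exhaustive surrogates and `target_count = 51`, the calibrated
#' test has family-wise false-positive probability at most 51/1024, i.e.
#' P <= 0.05 across the simultaneously tested components.
#'
#' @param surr A `surrogate_set` (>= 2 rows).
#' @param target_count Maximum tolerated family-wise false-positive count;
#'   default `floor(0.05 * nrow(surr))` (51 for 10 subjects).
#' @return List: `n`, `lower`/`upper` threshold vectors, `achieved_count`,
#'   `target_count`.
#' @export
calibrate_n <- function(surr, target_count = NULL) {
  M <- nrow(surr)
  stopifnot(M >= 2)
  if (is.null(target_count)) target_count <- floor(0.05 * M)
  n_max <- floor(M / 2)
  # achieved(1) = 0: no value is strictly outside the attained min/max.
  lo <- 1L; a_lo <- count_detections(surr, 1L)
  if (a_lo > target_count) stop("no rank satisfies the bound")  # unreachable
  hi <- n_max
  a_hi <- count_detections(surr, hi)
  if (a_hi <= target_count) {
    lo <- hi; a_lo <- a_hi
  } else {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      a_mid <- count_detections(surr, mid)
      if (a_mid < a_lo) stop("internal error: detection count not monotone in n")
      if (a_mid <= target_count) { lo <- mid; a_lo <- a_mid } else { hi <- mid; a_hi <- a_mid }
    }
  }
  sorted <- apply(surr, 2, sort)
  list(n = lo, lower = sorted[lo, ], upper = sorted[M - lo + 1, ],
       achieved_count = a_lo, target_count = target_count)
}

#' Compare the observed CPVE difference curve with surrogate thresholds
#'
#' Components whose observed difference lies strictly outside the calibrated
#' thresholds are flagged; the difference is declared significant (P < 0.05
#' family-wise, under the calibration) if at least one component is flagged.
#' The final component can never be flagged: both condition curves end at
#' 100, so its difference is identically zero.
#'
#' @param observed Observed difference curve (loud mean - quiet mean).
#' @param surr The `surrogate_set` used for calibration.
#' @param calibration Result of [calibrate_n()] on the same surrogate set.
#' @return Object of class `cpve_test`: list with `observed`, `lower`,
#'   `upper`, `n`, `achieved_count`, `target_count`, `flagged` (component
#'   indices) and `significant`.
#' @export
test_difference <- function(observed, surr, calibration) {
  stopifnot(length(observed) == ncol(surr))
  flagged <- which(observed < calibration$lower | observed > calibration$upper)
  structure(list(
    observed = as.numeric(observed),
    lower = calibration$lower, upper = calibration$upper,
    n = calibration$n, achieved_count = calibration$achieved_count,
    target_count = calibration$target_count,
    n_surrogates = nrow(surr),
    flagged = flagged, significant = length(flagged) > 0
  ), class = "cpve_test")
}

#' The full CPVE shuffle test
#'
#' Builds the exhaustive surrogate set from per-subject loud/quiet mean CPVE
#' curves, calibrates the rank threshold to the family-wise target, and
#' tests the observed loud-minus-quiet difference curve.
#'
#' @param loud,quiet Subjects x components matrices of mean CPVE curves.
#' @param target_count Family-wise false-positive target; default
#'   `floor(0.05 * 2^S)`.
#' @param seed Seed (used only for the S > 20 sampling fallback).
#' @return A `cpve_test` (see [test_difference()]), plus the achieved
#'   calibration details.
#' @export
cpve_shuffle_test <- function(loud, quiet, target_count = NULL, seed = 1) {
  surr <- surrogate_differences(loud, quiet, swaps = enumerate_swaps(nrow(as.matrix(loud)), seed))
  cal <- calibrate_n(surr, target_count)
  test_difference(surr[1, ], surr, cal)
}

#' @export
print.cpve_test <- function(x, ...) {
  cat("<cpve_test> n =", x$n, "| achieved", x$achieved_count, "of",
      x$n_surrogates, "surrogates (target", paste0(x$target_count, ")"), "\n")
  if (x$significant) {
    cat("significant difference; flagged component(s):",
        paste(x$flagged, collapse = ", "), "\n")
  } else {
    cat("no significant difference\n")
  }
  invisible(x)
}
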