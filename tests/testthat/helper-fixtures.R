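# Fixture builders and independent brute-force oracles used across the suite.
# Oracles are deliberately naive (explicit loops, closed forms) and share no
# code with the package implementation.

# A trial from an explicit signal matrix.
make_trial <- function(signal, sample_rate_hz = 1000, stimulus_time_ms = 200,
                       subject = "S01", task = 1, cue = "quiet", index = 1,
                       muscles = NULL) {
  if (is.null(muscles)) muscles <- paste0("m", seq_len(nrow(signal)))
  emg_trial(subject_id = subject, task_id = task, cue = cue,
            trial_index = index, stimulus_time_ms = stimulus_time_ms,
            sample_rate_hz = sample_rate_hz, muscles = muscles,
            signal = signal)
}

# Deterministic baseline with exact mean/SD (n-1), all values positive so
# rectification is the identity on it.
exact_baseline <- function(n, mean, sd) {
  z <- seq(-1.5, 1.5, length.out = n)
  z <- (z - mean(z)) / stats::sd(z)
  mean + sd * z
}

# A window_features table built directly (no signals): one row per trial and
# window, with supplied or random nonnegative muscle values.
make_feature_table <- function(subjects = "S01", tasks = 1:2, trials_per_cue = 3,
                               muscles = paste0("m", 1:5), windows = "0-10",
                               ert_fun = function(cue) if (cue == "loud") 80 else 150,
                               value_fun = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(value_fun)) {
    value_fun <- function(subject, task, cue, index) abs(rnorm(length(muscles))) + 0.1
  }
  rows <- list()
  for (s in subjects) for (task in tasks) for (cue in c("quiet", "loud"))
    for (k in seq_len(trials_per_cue)) for (w in windows) {
      v <- value_fun(s, task, cue, k)
      rows[[length(rows) + 1L]] <- c(
        list(subject_id = s, task_id = task, cue = cue, trial_index = k,
             ert_ms = ert_fun(cue), window = w),
        as.list(stats::setNames(v, muscles))
      )
    }
  dt <- data.table::rbindlist(rows)
  wdf <- data.frame(start_ms = 0, end_ms = 10, label = windows[1])
  structure(dt, muscles = muscles, windows = wdf,
            class = c("window_features", class(dt)))
}

# Naive reaction-time detector: explicit per-sample loops implementing the
# definition (rectify, optional centered running mean with shrinking edges,
# baseline mean + k*SD over [-baseline, 0), first strictly-supra-threshold
# run of at least min_above_ms starting in (0, search_limit]).
naive_detect <- function(trial, baseline_ms = 200, k_sd = 3,
                         search_limit_ms = 500, smooth_ms = 0, min_above_ms = 0) {
  fs <- trial$sample_rate_hz
  dt <- 1000 / fs
  n <- ncol(trial$signal)
  t <- (seq_len(n) - 1) * dt - trial$stimulus_time_ms
  nm <- nrow(trial$signal)
  thr <- num <- rep(NA_real_, nm)
  rt <- rep(NA_real_, nm)
  for (m in seq_len(nm)) {
    x <- abs(trial$signal[m, ])
    if (smooth_ms > 0) {
      w <- round(smooth_ms / dt)
      if (w %% 2 == 0) w <- w + 1
      half <- (w - 1) / 2
      sm <- vapply(seq_len(n), function(i) {
        mean(x[max(1, i - half):min(n, i + half)])
      }, numeric(1))
    } else {
      sm <- x
    }
    bi <- which(t >= -baseline_ms & t < 0)
    thr[m] <- mean(sm[bi]) + k_sd * stats::sd(sm[bi])
    d <- max(1, ceiling(min_above_ms / dt))
    for (i in which(t > 0 & t <= search_limit_ms)) {
      if (i + d - 1 <= n && all(sm[i:(i + d - 1)] > thr[m])) {
        rt[m] <- t[i]
        break
      }
    }
  }
  list(threshold = thr, rt_ms = rt)
}

# Exact two-sided rank-sum p-value by exhaustive enumeration of all
# assignments of the pooled sample to the two groups.
enumerate_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  ranks <- rank(pooled)
  obs <- sum(ranks[seq_len(n1)])
  idx <- utils::combn(length(pooled), n1)
  stats <- apply(idx, 2, function(i) sum(ranks[i]))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

# Brute-force sample covariance (double loop, n-1 denominator).
brute_cov <- function(m) {
  p <- ncol(m)
  out <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    xi <- m[, i] - mean(m[, i])
    xj <- m[, j] - mean(m[, j])
    out[i, j] <- sum(xi * xj) / (nrow(m) - 1)
  }
  out
}

# Linear-scan calibration oracle: largest rank n whose family-wise detection
# count stays at or below the target, counting detections naively for every
# candidate n.
scan_calibrate <- function(surr, target) {
  M <- nrow(surr)
  sorted <- apply(unclass(surr), 2, sort)
  best <- NULL
  counts <- integer(0)
  for (n in seq_len(floor(M / 2))) {
    hit <- rep(FALSE, M)
    for (k in seq_len(ncol(surr))) {
      hit <- hit | surr[, k] < sorted[n, k] | surr[, k] > sorted[M - n + 1, k]
    }
    counts[n] <- sum(hit)
    if (counts[n] <= target) best <- n
  }
  list(n = best, counts = counts)
}

# A plausible concave CPVE mean curve ending at 100 (used for curve-level
# simulations when no experiment is in play).
test_mean_curve <- function() {
  ev <- c(30, 20, 12, 8, 6, 5, 4, 3, 2.5, 2, 2, 1.8, 1.5, 1.2, 1)
  cumsum(ev) / sum(ev) * 100
}
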