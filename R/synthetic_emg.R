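#' Configuration for the synthetic EMG experiment generator
#'
#' Defaults mirror the design of a StartReact experiment: 10 subjects, 32
#' tasks, 5 trials per cue per task, 15 muscles sampled at 5 kHz, with trial
#' reaction times drawn per cue from truncated normal distributions
#' (quiet 204 +/- 79 ms, loud 144 +/- 75 ms, truncated below at 30 ms).
#'
#' Muscle activation is modelled as a nonnegative task pattern (a mixture of
#' `synergy_rank` shared subject-level synergy vectors) that modulates the
#' standard deviation of a zero-mean Gaussian carrier (amplitude-modulated
#' noise, the standard surrogate for interference-pattern EMG), on top of a
#' zero-mean Gaussian baseline of SD `noise_sd`. Mean rectified amplitude is
#' then proportional to the activation envelope, so window means are linear
#' in the pattern weights.
#'
#' @param n_subjects,n_tasks,trials_per_cue Experiment design counts.
#' @param muscles Muscle labels (default [default_muscles()]).
#' @param sample_rate_hz Sampling rate, default 5000.
#' @param rt_quiet_mean_ms,rt_quiet_sd_ms Quiet-cue reaction-time normal
#'   parameters (ms), defaults 204 and 79.
#' @param rt_loud_mean_ms,rt_loud_sd_ms Loud-cue reaction-time normal
#'   parameters (ms), defaults 144 and 75.
#' @param loud_slow_fraction Probability that a loud trial draws its reaction
#'   time from the quiet distribution, so that some loud trials exceed the
#'   100 ms exclusion cutoff. Default 0.15.
#' @param synergy_rank Number K of shared synergy vectors mixed into each
#'   task pattern (true fractionation dimensionality), 1..#muscles.
#' @param synergy_rank_loud Optional separate rank for loud-cue patterns; if
#'   `NULL` (default) loud trials reuse the quiet task patterns, making cue a
#'   pure reaction-time manipulation (the null structure).
#' @param pattern_sparsity Expected fraction of zero-weight muscles per task.
#' @param noise_sd Baseline Gaussian noise SD (amplitude units). Pattern
#'   weights are scaled so each task's strongest muscle has weight 1.
#' @param amp_jitter_sd SD of the per-trial multiplicative amplitude noise
#'   (amplitude = weight * (1 + noise)).
#' @param onset_ramp_ms Linear rise time from activation onset to plateau.
#' @param muscle_lag_max_ms Maximum uniform per-muscle onset lag beyond the
#'   trial's earliest onset. The task's strongest-weight muscle (the "prime
#'   mover") always has lag 0, so the programmed earliest onset is the
#'   minimum over per-muscle onsets.
#' @param pre_ms,post_ms Signal extent before/after the stimulus (ms).
#' @param seed Master seed; all randomness is split deterministically from it.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_subjects = 10, n_tasks = 32, trials_per_cue = 5,
                         muscles = default_muscles(), sample_rate_hz = 5000,
                         rt_quiet_mean_ms = 204, rt_quiet_sd_ms = 79,
                         rt_loud_mean_ms = 144, rt_loud_sd_ms = 75,
                         loud_slow_fraction = 0.15,
                         synergy_rank = 8, synergy_rank_loud = NULL,
                         pattern_sparsity = 0.4, noise_sd = 0.05,
                         amp_jitter_sd = 0.1, onset_ramp_ms = 10,
                         muscle_lag_max_ms = 20, pre_ms = 250, post_ms = 550,
                         seed = 1) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_tasks = as.integer(n_tasks),
    trials_per_cue = as.integer(trials_per_cue), muscles = muscles,
    sample_rate_hz = sample_rate_hz,
    rt_quiet_mean_ms = rt_quiet_mean_ms, rt_quiet_sd_ms = rt_quiet_sd_ms,
    rt_loud_mean_ms = rt_loud_mean_ms, rt_loud_sd_ms = rt_loud_sd_ms,
    loud_slow_fraction = loud_slow_fraction,
    synergy_rank = as.integer(synergy_rank),
    synergy_rank_loud = if (is.null(synergy_rank_loud)) NULL else as.integer(synergy_rank_loud),
    pattern_sparsity = pattern_sparsity, noise_sd = noise_sd,
    amp_jitter_sd = amp_jitter_sd, onset_ramp_ms = onset_ramp_ms,
    muscle_lag_max_ms = muscle_lag_max_ms, pre_ms = pre_ms, post_ms = post_ms,
    seed = as.integer(seed)
  )
  nm <- length(cfg$muscles)
  if (cfg$n_subjects < 1 || cfg$n_tasks < 1 || cfg$trials_per_cue < 1) {
    stop("design counts must be >= 1")
  }
  if (cfg$synergy_rank < 1 || cfg$synergy_rank > nm) {
    stop("synergy_rank must be in 1..", nm)
  }
  if (!is.null(cfg$synergy_rank_loud) &&
      (cfg$synergy_rank_loud < 1 || cfg$synergy_rank_loud > nm)) {
    stop("synergy_rank_loud must be in 1..", nm)
  }
  if (cfg$rt_quiet_mean_ms <= 0 || cfg$rt_loud_mean_ms <= 0) stop("rt means must be > 0")
  if (cfg$rt_quiet_sd_ms < 0 || cfg$rt_loud_sd_ms < 0 || cfg$noise_sd < 0 ||
      cfg$amp_jitter_sd < 0) stop("SDs must be >= 0")
  if (cfg$loud_slow_fraction < 0 || cfg$loud_slow_fraction > 1) {
    stop("loud_slow_fraction must be in [0, 1]")
  }
  if (cfg$pattern_sparsity < 0 || cfg$pattern_sparsity >= 1) {
    stop("pattern_sparsity must be in [0, 1)")
  }
  if (cfg$pre_ms < 200 || cfg$post_ms < 500) {
    stop("signal must span at least [-200, +500] ms around the stimulus")
  }
  structure(cfg, class = "synth_config")
}

# Normal truncated below at `lo` via rejection sampling.
rtnorm_lower <- function(n, mean, sd, lo = 30) {
  if (sd == 0) return(rep(max(mean, lo), n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo]
  }
  x
}

# Mean of a normal(mean, sd) truncated below at `lo` (closed form). Used by
# tests to state what the generator's realized reaction-time mean should be.
truncnorm_mean <- function(mean, sd, lo = 30) {
  if (sd == 0) return(max(mean, lo))
  a <- (lo - mean) / sd
  mean + sd * dnorm(a) / (1 - pnorm(a))
}

# Sparse nonnegative synergy basis. Each task mixes a random subset of the
# synergies (inclusion probability 1/2, at least one), so the set of silent
# muscles varies from task to task; muscle-synergy membership probability q
# solves (1 - q/2)^K = sparsity so that the expected fraction of zero-weight
# muscles per task matches `sparsity`. For small K the rank constraint can
# bind (q capped at 1) and the realized sparsity is lower; rank-1 patterns
# are necessarily proportional across tasks.
make_synergies <- function(n_muscles, K, sparsity) {
  q <- min(1, 2 * (1 - sparsity^(1 / K)))
  W <- matrix(abs(rnorm(n_muscles * K)), n_muscles, K)
  mask <- matrix(runif(n_muscles * K) < q, n_muscles, K)
  W <- W * mask
  for (k in seq_len(K)) {           # no empty synergy: rank must be exactly K
    if (all(W[, k] == 0)) W[sample.int(n_muscles, 1), k] <- abs(rnorm(1))
  }
  W
}

# Task patterns: nonnegative mixtures of a random subset of the synergy
# columns, rescaled so the strongest muscle of each task has weight 1.
make_patterns <- function(W, n_tasks) {
  K <- ncol(W)
  P <- matrix(0, nrow(W), n_tasks)
  for (t in seq_len(n_tasks)) {
    use <- runif(K) < 0.5
    if (!any(use)) use[sample.int(K, 1)] <- TRUE
    cvec <- (0.05 + abs(rnorm(K))) * use
    p <- as.vector(W %*% cvec)      # max(p) > 0: synergies are non-empty
    P[, t] <- p / max(p)
  }
  P
}

# One trial's signal and programmed onsets. Returns list(signal, onsets_ms,
# amplitudes). All times in ms relative to the stimulus.
synth_trial_signal <- function(pattern, rt_ms, cfg) {
  fs <- cfg$sample_rate_hz
  nm <- length(cfg$muscles)
  n <- as.integer(round((cfg$pre_ms + cfg$post_ms) * fs / 1000)) + 1L
  stim_idx <- as.integer(round(cfg$pre_ms * fs / 1000)) + 1L
  active <- which(pattern > 0)
  lags <- rep(NA_real_, nm)
  if (length(active)) {
    lags[active] <- runif(length(active), 0, cfg$muscle_lag_max_ms)
    lags[active[which.max(pattern[active])]] <- 0   # prime mover defines onset
  }
  jitter <- max(0.05, 1 + rnorm(1, 0, cfg$amp_jitter_sd))
  amps <- pattern * jitter
  onsets <- rt_ms + lags
  ramp_n <- max(1L, as.integer(round(cfg$onset_ramp_ms * fs / 1000)))
  onset_idx <- ifelse(is.na(onsets), NA_integer_,
                      stim_idx + as.integer(round(onsets * fs / 1000)))
  signal <- .cpp_synth_signal(nm, n, cfg$noise_sd, amps,
                              as.integer(onset_idx), ramp_n)
  list(signal = signal, onsets_ms = onsets, amplitudes = amps)
}

#' Generate a synthetic EMG experiment with known ground truth
#'
#' Builds a full trial set following the configured design, plus a ground
#' truth record of every programmed muscle onset and the task pattern
#' matrices, so downstream stages (onset detection, window features, CPVE,
#' similarity) can be validated against known answers.
#'
#' @param cfg A [synth_config()].
#' @param verbose Emit progress messages.
#' @return A list with elements `trials` (a [trial_set]) and `truth`, where
#'   `truth` holds `onsets` (data.table: subject_id, task_id, cue,
#'   trial_index, muscle, onset_ms, amplitude), `earliest` (data.table with
#'   the per-trial programmed earliest onset), `patterns` (per-subject
#'   muscle-by-task weight matrices, per cue) and `synergies`.
#' @export
generate_experiment <- function(cfg = synth_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "synth_config"))
  nm <- length(cfg$muscles)
  trials <- list()
  onset_rows <- list()
  earliest_rows <- list()
  patterns <- list()
  synergies <- list()
  for (s in seq_len(cfg$n_subjects)) {
    sid <- sprintf("S%02d", s)
    with_seed(split_seed(cfg$seed, "patterns", s), {
      W <- make_synergies(nm, cfg$synergy_rank, cfg$pattern_sparsity)
      Pq <- make_patterns(W, cfg$n_tasks)
      if (is.null(cfg$synergy_rank_loud)) {
        Wl <- W; Pl <- Pq
      } else {
        Wl <- make_synergies(nm, cfg$synergy_rank_loud, cfg$pattern_sparsity)
        Pl <- make_patterns(Wl, cfg$n_tasks)
      }
      synergies[[sid]] <- list(quiet = W, loud = Wl)
      patterns[[sid]] <- list(quiet = Pq, loud = Pl)
    })
    for (task in seq_len(cfg$n_tasks)) {
      for (cue in c("quiet", "loud")) {
        P <- patterns[[sid]][[cue]]
        for (k in seq_len(cfg$trials_per_cue)) {
          tr_seed <- split_seed(cfg$seed, "trial", s, task, cue, k)
          tr <- with_seed(tr_seed, {
            if (cue == "quiet") {
              rt <- rtnorm_lower(1, cfg$rt_quiet_mean_ms, cfg$rt_quiet_sd_ms)
            } else if (runif(1) < cfg$loud_slow_fraction) {
              rt <- rtnorm_lower(1, cfg$rt_quiet_mean_ms, cfg$rt_quiet_sd_ms)
            } else {
              rt <- rtnorm_lower(1, cfg$rt_loud_mean_ms, cfg$rt_loud_sd_ms)
            }
            out <- synth_trial_signal(P[, task], rt, cfg)
            out$rt <- rt
            out
          })
          trials[[length(trials) + 1L]] <- emg_trial(
            subject_id = sid, task_id = task, cue = cue, trial_index = k,
            stimulus_time_ms = cfg$pre_ms, sample_rate_hz = cfg$sample_rate_hz,
            muscles = cfg$muscles, signal = tr$signal
          )
          i <- length(trials)
          onset_rows[[i]] <- list(sid = sid, task = task, cue = cue, k = k,
                                  onsets = tr$onsets_ms, amps = tr$amplitudes)
          earliest_rows[[i]] <- min(tr$onsets_ms, na.rm = TRUE)
        }
      }
      if (verbose) msg("subject ", sid, " task ", task, " done")
    }
  }
  design <- list(subjects = cfg$n_subjects, tasks = cfg$n_tasks,
                 trials_per_cue = cfg$trials_per_cue)
  nm_rep <- length(cfg$muscles)
  onsets_dt <- data.table::data.table(
    subject_id = rep(vapply(onset_rows, `[[`, character(1), "sid"), each = nm_rep),
    task_id = rep(vapply(onset_rows, `[[`, integer(1), "task"), each = nm_rep),
    cue = rep(vapply(onset_rows, `[[`, character(1), "cue"), each = nm_rep),
    trial_index = rep(vapply(onset_rows, `[[`, integer(1), "k"), each = nm_rep),
    muscle = rep(cfg$muscles, length(onset_rows)),
    onset_ms = unlist(lapply(onset_rows, `[[`, "onsets"), use.names = FALSE),
    amplitude = unlist(lapply(onset_rows, `[[`, "amps"), use.names = FALSE)
  )
  earliest_dt <- data.table::data.table(
    subject_id = vapply(onset_rows, `[[`, character(1), "sid"),
    task_id = vapply(onset_rows, `[[`, integer(1), "task"),
    cue = vapply(onset_rows, `[[`, character(1), "cue"),
    trial_index = vapply(onset_rows, `[[`, integer(1), "k"),
    earliest_onset_ms = unlist(earliest_rows, use.names = FALSE)
  )
  list(
    trials = trial_set(trials, design = design,
                       provenance = list(generator = "synth_emg", seed = cfg$seed)),
    truth = list(onsets = onsets_dt, earliest = earliest_dt,
                 patterns = patterns, synergies = synergies, config = cfg)
  )
}

#' Generate paired per-subject CPVE curves with a known injected difference
#'
#' Draws, per subject, a condition-A and a condition-B CPVE curve as
#' `mean_curve` plus independent Gaussian component noise (`sd_curve`), with
#' `delta` (percentage points) added to condition B at `component` and all
#' later components, then capped at 100 -- a CPVE difference at one component
#' propagates cumulatively. Curves are forced nondecreasing and end at 100,
#' so they are valid inputs to [cpve_shuffle_test()].
#'
#' @param mean_curve Nondecreasing numeric vector ending at 100.
#' @param sd_curve Nonnegative numeric vector, same length.
#' @param n_subjects Number of subject pairs to draw.
#' @param delta Injected difference (percentage points) in condition B.
#' @param component 1-based component index at which `delta` is injected.
#' @param seed Seed for the draw.
#' @return List with matrices `a` and `b` (`n_subjects` rows, one column per
#'   component); condition B carries the injected difference.
#' @export
generate_cpve_samples <- function(mean_curve, sd_curve, n_subjects,
                                  delta = 0, component = 1, seed = 1) {
  k <- length(mean_curve)
  stopifnot(length(sd_curve) == k, all(sd_curve >= 0), n_subjects >= 1,
            component >= 1, component <= k)
  if (any(diff(mean_curve) < -1e-9)) stop("mean_curve must be nondecreasing")
  if (abs(mean_curve[k] - 100) > 1e-6) stop("mean_curve must end at 100")
  draw <- function(shift) {
    m <- matrix(rnorm(n_subjects * k, mean = rep(mean_curve, each = n_subjects),
                      sd = rep(sd_curve, each = n_subjects)),
                n_subjects, k)
    if (shift != 0) m[, component:k] <- m[, component:k] + shift
    m <- t(apply(m, 1, cummax))       # valid CPVE: nondecreasing, in [0, 100]
    m[m > 100] <- 100
    m[, k] <- 100
    m
  }
  with_seed(seed, list(a = draw(0), b = draw(delta)))
}

#' Power analysis for the CPVE shuffle test
#'
#' For each injected difference `delta`, simulates replicate experiments with
#' [generate_cpve_samples()] and reports the fraction in which
#' [cpve_shuffle_test()] declares a significant difference, with its Monte
#' Carlo standard error. At `delta = 0` this estimates the test's achieved
#' level (about 0.05 when calibrated to 51/1,024 for 10 subjects).
#'
#' @inheritParams generate_cpve_samples
#' @param deltas Numeric vector of injected differences (percentage points).
#' @param replicates Replicate experiments per delta (>= 100).
#' @param target_count Family-wise false-positive target passed to the test;
#'   default `floor(0.05 * 2^n_subjects)`.
#' @return data.frame with columns delta, power, se, replicates.
#' @export
power_analysis <- function(mean_curve, sd_curve, n_subjects, deltas,
                           component = 1, replicates = 200,
                           target_count = NULL, seed = 1) {
  stopifnot(replicates >= 100)
  res <- lapply(deltas, function(d) {
    hits <- 0L
    for (r in seq_len(replicates)) {
      sim <- generate_cpve_samples(mean_curve, sd_curve, n_subjects,
                                   delta = d, component = component,
                                   seed = split_seed(seed, "power", round(d * 1e6), r))
      tst <- cpve_shuffle_test(loud = sim$b, quiet = sim$a,
                               target_count = target_count)
      if (tst$significant) hits <- hits + 1L
    }
    p <- hits / replicates
    data.frame(delta = d, power = p, se = sqrt(p * (1 - p) / replicates),
               replicates = replicates)
  })
  do.call(rbind, res)
}
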