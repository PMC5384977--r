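#' The default set of 15 upper-limb muscles
#'
#' Muscle labels used throughout the package, covering intrinsic hand muscles,
#' wrist/finger flexors and extensors, elbow flexors/extensor and shoulder
#' muscles: first dorsal interosseous (1DI), abductor pollicis brevis (AbPB),
#' abductor digiti minimi (AbDM), flexor digitorum superficialis (FDS), flexor
#' carpi ulnaris (FCU), flexor carpi radialis (FCR), extensor carpi ulnaris
#' (ECU), extensor carpi radialis (ECR), extensor digitorum communis (EDC),
#' brachialis (BR), biceps (BIC), triceps (TRI), anterior deltoid (ADel),
#' posterior deltoid (PDel) and pectoralis major (PMaj).
#'
#' @return Character vector of 15 muscle labels.
#' @export
default_muscles <- function() {
  c("1DI", "AbPB", "AbDM", "FDS", "FCU", "FCR", "ECU", "ECR", "EDC",
    "BR", "BIC", "TRI", "ADel", "PDel", "PMaj")
}

#' Construct a single EMG trial
#'
#' A trial is the atomic unit of the pipeline: one cued movement, holding a
#' muscles-by-samples signal array plus metadata. Sample `i` of the signal is
#' at time `(i - 1) * 1000 / sample_rate_hz` ms from the start of the trace;
#' the cue (stimulus) occurs at `stimulus_time_ms` on that axis. The trace
#' must span at least 200 ms before and 500 ms after the stimulus so that
#' baseline statistics and the post-stimulus search window are always covered.
#'
#' @param subject_id,task_id,cue,trial_index Trial key. `cue` must be
#'   `"quiet"` or `"loud"`; `trial_index` is a positive integer.
#' @param stimulus_time_ms Stimulus time in ms from the first sample.
#' @param sample_rate_hz Sampling rate (samples/second), default 5000.
#' @param muscles Character vector of unique muscle labels, one per signal row.
#' @param signal Numeric matrix, `length(muscles)` rows, signed EMG amplitude.
#' @return An object of class `emg_trial`.
#' @export
emg_trial <- function(subject_id, task_id, cue, trial_index, stimulus_time_ms,
                      sample_rate_hz = 5000, muscles, signal) {
  stopifnot(is.matrix(signal), nrow(signal) == length(muscles))
  if (anyDuplicated(muscles)) stop("muscle labels must be unique")
  if (!cue %in% c("quiet", "loud")) stop("cue must be 'quiet' or 'loud'")
  if (!is.finite(sample_rate_hz) || sample_rate_hz <= 0) stop("sample_rate_hz must be > 0")
  if (trial_index < 1) stop("trial_index must be >= 1")
  if (anyNA(signal)) stop("missing values are forbidden in signals")
  dur_ms <- (ncol(signal) - 1) * 1000 / sample_rate_hz
  if (stimulus_time_ms < 200 || dur_ms - stimulus_time_ms < 500) {
    stop("signal must span at least [-200, +500] ms around the stimulus")
  }
  rownames(signal) <- muscles
  structure(list(
    subject_id = as.character(subject_id), task_id = as.integer(task_id),
    cue = cue, trial_index = as.integer(trial_index),
    stimulus_time_ms = as.numeric(stimulus_time_ms),
    sample_rate_hz = as.numeric(sample_rate_hz),
    muscles = as.character(muscles), signal = signal
  ), class = "emg_trial")
}

trial_key <- function(trial) {
  paste(trial$subject_id, trial$task_id, trial$cue, trial$trial_index, sep = "|")
}

#' Construct a trial set
#'
#' A collection of [emg_trial] objects sharing one muscle ordering, with
#' design metadata and provenance. The (subject, task, cue, trial_index) key
#' must be unique across the set.
#'
#' @param trials List of `emg_trial` objects.
#' @param design Optional list of design metadata (subjects, tasks,
#'   trials per cue).
#' @param provenance Optional list (generator seed or source path).
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(trials, design = NULL, provenance = NULL) {
  stopifnot(is.list(trials))
  keys <- vapply(trials, trial_key, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate trial key: ", keys[duplicated(keys)][1])
  }
  if (length(trials) > 1) {
    m0 <- trials[[1]]$muscles
    for (tr in trials[-1]) {
      if (!identical(tr$muscles, m0)) {
        stop("inconsistent muscle ordering in trial ", trial_key(tr))
      }
    }
  }
  structure(list(trials = trials, design = design, provenance = provenance),
            class = "trial_set")
}

#' @export
length.trial_set <- function(x) length(x$trials)

#' @export
print.trial_set <- function(x, ...) {
  cat("<trial_set>", length(x$trials), "trials")
  if (length(x$trials)) {
    cat(";", length(x$trials[[1]]$muscles), "muscles @",
        x$trials[[1]]$sample_rate_hz, "Hz")
  }
  cat("\n")
  invisible(x)
}

#' Write a trial set to a directory
#'
#' Emits `trials.csv` (one row per trial: subject_id, task_id, cue,
#' trial_index, stimulus_time_ms, sample_rate_hz, signal_file) plus one CSV
#' per trial whose first column is `time_ms` and remaining columns are the
#' muscles, in set order. Values are written with full double precision
#' (>= 15 significant digits); the layout is plain comma-separated UTF-8 with
#' a header row and '.' decimal so sets are human-inspectable and diff-able.
#'
#' @param set A [trial_set].
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @seealso [read_trialset()]
#' @export
write_trialset <- function(set, path) {
  stopifnot(inherits(set, "trial_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory ", path)
  meta <- data.table::data.table(
    subject_id = character(), task_id = integer(), cue = character(),
    trial_index = integer(), stimulus_time_ms = numeric(),
    sample_rate_hz = numeric(), signal_file = character()
  )
  for (tr in set$trials) {
    fn <- sprintf("signal_%s_%03d_%s_%02d.csv",
                  tr$subject_id, tr$task_id, tr$cue, tr$trial_index)
    time_ms <- (seq_len(ncol(tr$signal)) - 1) * 1000 / tr$sample_rate_hz
    sig <- data.table::as.data.table(t(tr$signal))
    data.table::setnames(sig, tr$muscles)
    out <- data.table::data.table(time_ms = time_ms)
    out <- cbind(out, sig)
    data.table::fwrite(out, file.path(path, fn))
    meta <- rbind(meta, data.table::data.table(
      subject_id = tr$subject_id, task_id = tr$task_id, cue = tr$cue,
      trial_index = tr$trial_index, stimulus_time_ms = tr$stimulus_time_ms,
      sample_rate_hz = tr$sample_rate_hz, signal_file = fn
    ))
  }
  data.table::fwrite(meta, file.path(path, "trials.csv"))
  invisible(path)
}

#' Read a trial set from a directory
#'
#' Inverse of [write_trialset()]: reads `trials.csv` and the per-trial signal
#' files it references. Validation failures (missing signal file, duplicate
#' keys, inconsistent muscle ordering) raise errors naming the offending
#' trial.
#'
#' @param path Directory produced by [write_trialset()] or conforming to its
#'   documented CSV dialect.
#' @return A [trial_set].
#' @export
read_trialset <- function(path) {
  mf <- file.path(path, "trials.csv")
  if (!file.exists(mf)) stop("missing metadata file ", mf)
  meta <- data.table::fread(mf, colClasses = list(character = "subject_id"))
  trials <- vector("list", nrow(meta))
  if (nrow(meta)) {
    for (i in seq_len(nrow(meta))) {
      row <- meta[i]
      key <- paste(row$subject_id, row$task_id, row$cue, row$trial_index, sep = "|")
      sf <- file.path(path, row$signal_file)
      if (!file.exists(sf)) stop("trial ", key, ": missing signal file ", row$signal_file)
      sig <- data.table::fread(sf)
      if (names(sig)[1] != "time_ms") stop("trial ", key, ": first signal column must be time_ms")
      muscles <- names(sig)[-1]
      smat <- t(as.matrix(sig[, -1]))
      trials[[i]] <- emg_trial(
        subject_id = row$subject_id, task_id = row$task_id, cue = row$cue,
        trial_index = row$trial_index, stimulus_time_ms = row$stimulus_time_ms,
        sample_rate_hz = row$sample_rate_hz, muscles = muscles, signal = smat
      )
    }
  }
  trial_set(trials, provenance = list(source = path))
}
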