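test_that("window means recover constant and ramped rectified levels", {
  fs <- 5000
  n <- 4001
  tr_const <- make_trial(matrix(2.5, 2, n), sample_rate_hz = fs,
                         stimulus_time_ms = 250)
  wm <- window_means(tr_const, ert_ms = 120)
  expect_equal(dim(wm), c(4, 2))
  expect_true(all(abs(wm - 2.5) < 1e-12))

  # level rising linearly from 0 at eRT to 10 at eRT+10 ms: mean over the
  # half-open 0-10 ms window is 5 up to one-sample discretization
  t_ms <- (seq_len(n) - 1) * 1000 / fs - 250
  ramp <- pmax(0, pmin(t_ms - 120, 10))
  tr_ramp <- make_trial(matrix(ramp, 1, byrow = TRUE), sample_rate_hz = fs,
                        stimulus_time_ms = 250)
  wm2 <- window_means(tr_ramp, ert_ms = 120)
  expect_lt(abs(wm2["0-10", 1] - 5), 10 / (10 * fs / 1000))
  expect_error(window_means(tr_ramp, ert_ms = NA), "ert missing")
  expect_error(window_means(tr_ramp, ert_ms = 500), "too short")
})

test_that("every trial with a detected eRT yields one nonnegative vector per window", {
  gen <- generate_experiment(
    synth_config(n_subjects = 1, n_tasks = 2, trials_per_cue = 2,
                 rt_quiet_mean_ms = 120, rt_quiet_sd_ms = 15,
                 rt_loud_mean_ms = 70, rt_loud_sd_ms = 10,
                 loud_slow_fraction = 0, seed = 3))
  on <- detect_onsets(gen$trials, smooth_ms = 5, min_above_ms = 10)
  feats <- extract_features(gen$trials, on)
  expect_equal(nrow(feats), 8 * 4)   # 8 trials x 4 windows
  m <- as.matrix(feats[, attr(feats, "muscles"), with = FALSE])
  expect_true(all(m >= 0))
})

test_that("loud trials over the cutoff are excluded with matched random quiet trials", {
  tr <- data.table::data.table(
    subject_id = "S01",
    task_id = rep(1L, 6), cue = rep(c("loud", "quiet"), each = 3),
    trial_index = rep(1:3, 2),
    ert_ms = c(90, 110, 95, 150, 160, 170)
  )
  em <- exclude_and_match(tr, cutoff_ms = 100, seed = 4)
  expect_equal(sum(em$excluded$reason == "loud_ert_over_cutoff"), 1)
  expect_equal(sum(em$excluded$reason == "quiet_random_match"), 1)
  expect_equal(sum(em$kept$cue == "loud"), sum(em$kept$cue == "quiet"))

  none <- tr[c(1, 3, 4, 5), ]   # balanced: 2 fast loud, 2 quiet
  em0 <- exclude_and_match(none, cutoff_ms = 100, seed = 4)
  expect_equal(nrow(em0$excluded), 0)
  expect_equal(nrow(em0$kept), 4)

  all_slow <- data.table::copy(tr)
  all_slow$ert_ms[all_slow$cue == "loud"] <- 200
  all_slow <- all_slow[c(1:3, 4), ]   # 3 slow loud, 1 quiet
  expect_error(exclude_and_match(all_slow, cutoff_ms = 100, seed = 1),
               "more loud exclusions")
})

test_that("matched quiet exclusion draws each quiet trial uniformly", {
  tr <- data.table::data.table(
    subject_id = "S01", task_id = 1L,
    cue = c("loud", rep("quiet", 6)), trial_index = 1:7,
    ert_ms = c(140, rep(80, 6))
  )
  picks <- integer(6)
  for (seed in 1:1200) {
    em <- exclude_and_match(tr, cutoff_ms = 100, seed = seed)
    gone <- em$excluded[em$excluded$reason == "quiet_random_match", ]
    picks[gone$trial_index - 1L] <- picks[gone$trial_index - 1L] + 1L
  }
  expect_equal(sum(picks), 1200)
  se <- sqrt(1200 * (1 / 6) * (5 / 6))
  expect_true(all(abs(picks - 200) < 4 * se))
})

test_that("missing-eRT trials are dropped first and cue counts stay balanced", {
  tr <- data.table::data.table(
    subject_id = "S01", task_id = 1L,
    cue = rep(c("loud", "quiet"), each = 4), trial_index = rep(1:4, 2),
    ert_ms = c(90, NA, 95, 80, 150, 160, 170, 155)
  )
  expect_warning(em <- exclude_and_match(tr, cutoff_ms = 100, seed = 2),
                 "without eRT")
  expect_equal(sum(em$kept$cue == "loud"), sum(em$kept$cue == "quiet"))
})

test_that("condition matrices stack the feature vectors in deterministic order", {
  feats <- make_feature_table(tasks = 1:3, trials_per_cue = 5, seed = 10)
  kept <- unique(feats[, c("subject_id", "task_id", "cue", "trial_index", "ert_ms")])
  m <- build_condition_matrix(feats, kept, "S01", "quiet", "0-10")
  expect_equal(dim(m), c(15, 5))
  expect_false(attr(m, "zscored"))
  # identity audit: every row equals its trial's feature vector
  muscles <- attr(feats, "muscles")
  keys <- attr(m, "trial_keys")
  for (i in seq_len(nrow(m))) {
    sel <- feats$task_id == keys$task_id[i] & feats$trial_index == keys$trial_index[i] &
      feats$cue == "quiet" & feats$window == "0-10"
    expect_equal(unname(m[i, ]),
                 unname(as.numeric(as.matrix(feats[which(sel), muscles, with = FALSE]))))
  }
  one <- build_condition_matrix(feats, kept[kept$task_id == 1 & kept$cue == "quiet", ],
                                "S01", "quiet", "0-10")
  expect_equal(nrow(one), 5)
})

test_that("z-scoring standardizes columns, flags degenerate ones, and is idempotent", {
  feats <- make_feature_table(tasks = 1, trials_per_cue = 3, seed = 2)
  kept <- unique(feats[, c("subject_id", "task_id", "cue", "trial_index", "ert_ms")])
  m <- build_condition_matrix(feats, kept, "S01", "quiet", "0-10")
  m[, 1] <- c(1, 2, 3)
  m[, 2] <- 7                       # constant column
  z <- zscore_columns(m)
  expect_equal(unname(z[, 1]), c(-1, 0, 1))
  expect_equal(unname(z[, 2]), c(0, 0, 0))
  expect_true(attr(z, "degenerate")[2])
  expect_false(attr(z, "degenerate")[1])
  expect_true(all(abs(colMeans(z)) < 1e-9))
  z2 <- zscore_columns(z)
  expect_equal(unclass(z2)[, ], unclass(z)[, ], tolerance = 1e-12)
  expect_error(zscore_columns(m[1, , drop = FALSE]), "2 rows")
})
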