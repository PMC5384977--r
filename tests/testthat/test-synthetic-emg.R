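fast_cfg <- function(...) {
  defaults <- list(n_subjects = 1, n_tasks = 4, trials_per_cue = 3,
                   rt_quiet_mean_ms = 120, rt_quiet_sd_ms = 20,
                   rt_loud_mean_ms = 70, rt_loud_sd_ms = 10,
                   loud_slow_fraction = 0, seed = 5)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

test_that("config validation rejects out-of-range parameters", {
  expect_error(synth_config(synergy_rank = 0), "synergy_rank")
  expect_error(synth_config(synergy_rank = 16), "synergy_rank")
  expect_error(synth_config(loud_slow_fraction = 1.2), "loud_slow_fraction")
  expect_error(synth_config(rt_quiet_mean_ms = -1), "rt means")
  expect_error(synth_config(noise_sd = -0.1), "SDs")
  expect_error(synth_config(pre_ms = 100), "-200")
})

test_that("programmed earliest onset equals the minimum over muscle onsets", {
  gen <- generate_experiment(fast_cfg())
  on <- gen$truth$onsets
  ea <- gen$truth$earliest
  for (i in seq_len(nrow(ea))) {
    sel <- on$subject_id == ea$subject_id[i] & on$task_id == ea$task_id[i] &
      on$cue == ea$cue[i] & on$trial_index == ea$trial_index[i]
    expect_equal(min(on$onset_ms[sel], na.rm = TRUE), ea$earliest_onset_ms[i])
  }
  expect_true(all(ea$earliest_onset_ms >= 30))
})

test_that("identical seeds give byte-identical trial sets on disk", {
  g1 <- generate_experiment(fast_cfg())
  g2 <- generate_experiment(fast_cfg())
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_trialset(g1$trials, d1)
  write_trialset(g2$trials, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  g3 <- generate_experiment(fast_cfg(seed = 6))
  expect_false(identical(g1$trials$trials[[1]]$signal,
                         g3$trials$trials[[1]]$signal))
})

test_that("baseline rectified level is below activation level for active muscles", {
  gen <- generate_experiment(fast_cfg())
  for (tr_i in c(1, 5, 9)) {
    tr <- gen$trials$trials[[tr_i]]
    ea <- gen$truth$earliest[tr_i]
    t_ms <- (seq_len(ncol(tr$signal)) - 1) * 1000 / tr$sample_rate_hz -
      tr$stimulus_time_ms
    on <- gen$truth$onsets[
      gen$truth$onsets$subject_id == tr$subject_id &
        gen$truth$onsets$task_id == tr$task_id &
        gen$truth$onsets$cue == tr$cue &
        gen$truth$onsets$trial_index == tr$trial_index]
    for (m in which(!is.na(on$onset_ms))) {
      base <- mean(abs(tr$signal[m, t_ms < 0]))
      act <- mean(abs(tr$signal[m, t_ms > on$onset_ms[m] + 15]))
      expect_gt(act, base)
    }
  }
})

test_that("a noiseless single-muscle trial is detected at its programmed onset", {
  cfg <- synth_config(n_subjects = 1, n_tasks = 1, trials_per_cue = 1,
                      muscles = "m1", noise_sd = 0, amp_jitter_sd = 0,
                      rt_quiet_mean_ms = 150, rt_quiet_sd_ms = 0,
                      rt_loud_mean_ms = 150, rt_loud_sd_ms = 0,
                      loud_slow_fraction = 0, synergy_rank = 1,
                      muscle_lag_max_ms = 0, seed = 2)
  gen <- generate_experiment(cfg)
  tr <- gen$trials$trials[[1]]
  res <- detect_rt(tr)   # plain single-sample rule: zero baseline noise
  expect_equal(res$ert_ms, gen$truth$earliest$earliest_onset_ms[1],
               tolerance = 1e-9)
})

test_that("rank-1 task patterns concentrate CPVE in the first component", {
  # with rank-1 patterns every z-scored column shares the trial amplitude
  # factor; its variance must dominate the ~5% carrier sampling noise of the
  # window means (correlation jitter^2/(jitter^2 + 0.048^2)), so trial-to-
  # trial amplitude variability is set high relative to that noise floor
  cfg <- fast_cfg(n_tasks = 6, trials_per_cue = 4, synergy_rank = 1,
                  noise_sd = 0.01, amp_jitter_sd = 0.35)
  gen <- generate_experiment(cfg)
  on <- detect_onsets(gen$trials, smooth_ms = 5, min_above_ms = 10)
  feats <- extract_features(gen$trials, on)
  em <- exclude_and_match(unique(feats[feats$window == "50-100",
    c("subject_id", "task_id", "cue", "trial_index", "ert_ms")]), seed = 1)
  m <- build_condition_matrix(feats, em$kept, "S01", "quiet", "50-100")
  curve <- cpve_from_covariance(covariance_matrix(zscore_columns(m)))
  expect_gt(curve[1], 95)
})

test_that("generated CPVE sample pairs are valid curves with the injected difference", {
  mc <- test_mean_curve()
  sim0 <- generate_cpve_samples(mc, rep(0, 15), n_subjects = 4, delta = 0, seed = 9)
  expect_equal(sim0$a, sim0$b)
  expect_equal(unname(sim0$a[1, ]), mc)
  sim <- generate_cpve_samples(mc, rep(1.5, 15), n_subjects = 8, delta = 6,
                               component = 3, seed = 9)
  for (cond in sim) {
    expect_true(all(diff(t(cond)) >= -1e-12))
    expect_true(all(abs(cond[, 15] - 100) < 1e-9))
    expect_true(all(cond <= 100 + 1e-9))
  }
  # injected shift visible at the target component
  expect_gt(mean(sim$b[, 3] - sim$a[, 3]), 2)
  expect_error(generate_cpve_samples(rev(mc), rep(1, 15), 4), "nondecreasing")
})

test_that("power is the test level at zero delta, monotone, and 1 without noise", {
  mc <- test_mean_curve()
  pw <- power_analysis(mc, rep(1.5, 15), n_subjects = 10,
                       deltas = c(0, 4, 10), component = 2,
                       replicates = 150, seed = 21)
  expect_equal(pw$delta, c(0, 4, 10))
  expect_lt(pw$power[1], 0.15)          # calibrated level ~0.05
  expect_gt(pw$power[3], pw$power[1])   # monotone within Monte Carlo error
  expect_gte(pw$power[3] + 3 * pw$se[3], pw$power[2])
  pw0 <- power_analysis(mc, rep(0, 15), n_subjects = 10, deltas = 5,
                        component = 2, replicates = 100, seed = 3)
  expect_equal(pw0$power, 1)
})
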