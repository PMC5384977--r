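zmat <- function(m) {
  attr(m, "zscored") <- TRUE
  m
}

test_that("covariance matches a brute-force double loop and known structures", {
  set.seed(1)
  m <- matrix(rnorm(12), 4, 3)
  z <- zscore_columns(structure(m, zscored = FALSE))
  cv <- covariance_matrix(z)
  expect_equal(cv, brute_cov(z[, ]), ignore_attr = TRUE)
  expect_equal(cv, t(cv), ignore_attr = TRUE)
  expect_equal(unname(diag(cv)), rep(1, 3), tolerance = 1e-12)

  dup <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4) * 2, c = c(4, 1, 3, 2))
  zd <- zscore_columns(structure(dup, zscored = FALSE))
  cvd <- covariance_matrix(zd)
  expect_equal(cvd["a", "b"], 1, tolerance = 1e-12)   # identical after z-scoring

  set.seed(2)
  big <- matrix(rnorm(10000 * 4), ncol = 4)
  cvb <- covariance_matrix(zmat(scale(big)))
  expect_true(all(abs(cvb[upper.tri(cvb)]) < 0.05))
  expect_error(covariance_matrix(m), "z-scored")
})

test_that("CPVE of an identity covariance is k * 100/15 and of rank-1 is all 100", {
  curve <- cpve_from_covariance(diag(15))
  expect_equal(unclass(curve), (1:15) * (100 / 15))
  expect_equal(curve[1], 100 / 15, tolerance = 1e-12)

  v <- c(3, 1, 0.5, rep(0.2, 12))
  r1 <- cpve_from_covariance(outer(v, v))
  expect_equal(unclass(r1), rep(100, 15), tolerance = 1e-9)
})

test_that("CPVE eigenvalues agree with the characteristic-polynomial roots", {
  C <- matrix(c(4, 1, 0.5,
                1, 3, 0.2,
                0.5, 0.2, 2), 3, 3, byrow = TRUE)
  # det(C - x I) = -x^3 + tr x^2 - (sum of principal 2x2 minors) x + det
  tr <- sum(diag(C))
  minors <- det(C[1:2, 1:2]) + det(C[c(1, 3), c(1, 3)]) + det(C[2:3, 2:3])
  roots <- sort(Re(polyroot(c(det(C), -minors, tr, -1))), decreasing = TRUE)
  expect_equal(unclass(cpve_from_covariance(C)),
               cumsum(roots) / sum(roots) * 100, tolerance = 1e-8)
})

test_that("CPVE curves are nondecreasing and end at 100 on random inputs", {
  set.seed(3)
  for (i in 1:20) {
    m <- matrix(rnorm(30 * 6), 30, 6) %*% diag(runif(6, 0.1, 3))
    curve <- cpve_from_covariance(covariance_matrix(zmat(scale(m))))
    expect_true(all(diff(curve) >= -1e-9))
    expect_equal(curve[length(curve)], 100, tolerance = 1e-6)
    expect_gte(curve[1], 100 / 6 - 1e-9)   # first component of z-scored data
  }
  expect_error(cpve_from_covariance(matrix(0, 3, 3)), "zero total variance")
  expect_error(cpve_from_covariance(diag(c(1, -1, 1))), "positive semi-definite")
  expect_error(cpve_from_covariance(matrix(c(1, 5, 0, 1), 2, 2)), "symmetric")
})

test_that("rank-K activation vectors give CPVE exactly 100 by component K", {
  K <- 3
  set.seed(19)
  B <- matrix(abs(rnorm(5 * K)) + 0.05, 5, K)   # 5 muscles, 3 synergies
  feats <- make_feature_table(tasks = 1:8, trials_per_cue = 4, seed = 19,
    value_fun = function(s, task, cue, k) as.vector(B %*% (abs(rnorm(K)) + 0.05)))
  kept <- unique(feats[, c("subject_id", "task_id", "cue", "trial_index", "ert_ms")])
  m <- build_condition_matrix(feats, kept, "S01", "quiet", "0-10")
  curve <- cpve_from_covariance(covariance_matrix(zscore_columns(m)))
  expect_equal(unname(curve[K]), 100, tolerance = 1e-6)
})

test_that("the full generator chain recovers the synergy rank as a CPVE elbow", {
  # the amplitude-modulated carrier leaves an irreducible ~5% sampling noise
  # on each 50-ms window mean, so CPVE_K sits just below 100 even with
  # near-zero baseline noise; the curve must be high at K and flat beyond
  K <- 3
  cfg <- synth_config(n_subjects = 1, n_tasks = 16, trials_per_cue = 5,
                      rt_quiet_mean_ms = 120, rt_quiet_sd_ms = 15,
                      rt_loud_mean_ms = 70, rt_loud_sd_ms = 10,
                      loud_slow_fraction = 0, synergy_rank = K,
                      pattern_sparsity = 0, noise_sd = 1e-3, seed = 13)
  gen <- generate_experiment(cfg)
  on <- detect_onsets(gen$trials, smooth_ms = 5, min_above_ms = 10)
  feats <- extract_features(gen$trials, on)
  trials <- unique(feats[feats$window == "50-100",
    c("subject_id", "task_id", "cue", "trial_index", "ert_ms")])
  em <- exclude_and_match(trials, seed = 1)
  m <- build_condition_matrix(feats, em$kept, "S01", "quiet", "50-100")
  curve <- cpve_from_covariance(covariance_matrix(zscore_columns(m)))
  expect_gte(curve[K], 95)
  expect_lt(curve[K + 1] - curve[K], 1.5)         # flat past the true rank
  expect_gt(curve[K] - curve[K - 1], 5)           # still rising at the rank
})

test_that("exclusion-averaged CPVE is stable without exclusions and averages over them", {
  # no loud eRT over the cutoff: every repeat must be identical
  feats <- make_feature_table(tasks = 1:4, trials_per_cue = 4, seed = 6)
  av <- averaged_cpve(feats, "S01", "0-10", repeats = 5, base_seed = 2)
  one <- averaged_cpve(feats, "S01", "0-10", repeats = 1, base_seed = 99)
  expect_equal(unclass(av$quiet), unclass(one$quiet), tolerance = 1e-12)
  expect_equal(av$quiet_sd, rep(0, 5), tolerance = 1e-12)

  # slow loud trials force random quiet exclusion: quiet curve varies by
  # repeat, loud curve does not
  feats2 <- make_feature_table(tasks = 1:4, trials_per_cue = 4, seed = 7,
    ert_fun = function(cue) if (cue == "loud") sample(c(80, 130), 1) else 150)
  av2 <- averaged_cpve(feats2, "S01", "0-10", repeats = 20, base_seed = 3)
  expect_gt(max(av2$quiet_sd), 0)
  expect_true(all(diff(av2$quiet) >= -1e-9))
  expect_equal(av2$quiet[5], 100, tolerance = 1e-9)
  expect_equal(av2$n_trials[["quiet"]], av2$n_trials[["loud"]])
})
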