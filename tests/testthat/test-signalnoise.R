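test_that("pair indices map to the right classes", {
  ses <- small_session()
  expect_equal(placecode:::pair_classes(ses$tensor, 1), c(1L, 2L))
  expect_equal(placecode:::pair_classes(ses$tensor, 19), c(19L, 20L))
  expect_equal(placecode:::pair_classes(ses$tensor, 20), c(21L, 22L))
  expect_equal(placecode:::pair_classes(ses$tensor, 38), c(39L, 40L))
  expect_error(placecode:::pair_classes(ses$tensor, 39), "out of range")
})

test_that("the signal direction is the normalized mean difference", {
  tens <- tiny_tensor()
  sd1 <- signal_direction(tens, 1)
  m1 <- rowMeans(tens$values[, 1, ])
  m2 <- rowMeans(tens$values[, 2, ])
  expect_equal(sd1$dmu, unname(m2 - m1), tolerance = 1e-12)
  expect_equal(sum(sd1$unit^2), 1, tolerance = 1e-12)
  expect_equal(sd1$norm, sqrt(sum((m2 - m1)^2)), tolerance = 1e-12)
})

test_that("cross-validated estimates recover the ground truth", {
  # many trials so the CV estimates concentrate near their targets; the
  # signal estimate is biased low by the training-direction estimation
  # error (a cos^2 factor), which shrinks as trials grow
  cfg <- synth_config(n_neurons = 30, n_trials_per_direction = 1600,
                      width_dist = list(kind = "uniform", min = 1, max = 2),
                      amp_dist = list(kind = "constant", value = 1),
                      indep_noise_var = 0.3,
                      limited_range = list(c = 0, lambda_d = 2),
                      differential_eps = 0.2, seed = 41)
  ses <- simulate_session(cfg)
  pair <- 10
  est <- cv_signal_noise(ses$tensor, pair, seed = 2)
  dmu <- ses$tuning$signal_vectors[, pair]
  u <- dmu / sqrt(sum(dmu^2))
  Sigma <- ses$noise[[pair]]$covariance
  expect_equal(unname(est["signal"]), sum(dmu^2), tolerance = 0.15)
  expect_equal(unname(est["noise"]), drop(u %*% Sigma %*% u),
               tolerance = 0.15)
  expect_equal(unname(est["snr"]),
               unname(est["signal"] / est["noise"]), tolerance = 1e-12)
})

test_that("motion-direction SNR separates opposite-direction fields", {
  ses <- small_session()
  mot <- motion_direction_snr(ses$tensor, position_bin = 10, seed = 3)
  expect_named(mot, c("signal", "noise", "snr"))
  # directional place fields are drawn independently -> strong signal
  expect_gt(mot["snr"], 1)
  expect_error(motion_direction_snr(ses$tensor, position_bin = 20))
})

test_that("snr_size_curves returns curves, slopes and their ratio", {
  ses <- small_session()
  rec <- snr_size_curves(ses$tensor, sizes = c(20, 30, 40), n_subsets = 3,
                         seed = 5, slope_min_size = 15)
  expect_s3_class(rec, "snr_record")
  expect_equal(rec$curve$size, c(20, 30, 40))
  expect_equal(rec$asymptotic_snr, rec$signal_slope / rec$noise_slope)
  expect_true(all(rec$curve$noise > 0))
  # signal grows with ensemble size
  expect_gt(rec$curve$signal[3], rec$curve$signal[1])
  expect_error(snr_size_curves(ses$tensor, sizes = c(20, 30), n_subsets = 2,
                               seed = 1, slope_min_size = 100),
               "at least 2 sizes")
})

test_that("single-cell SNR matches a direct ANOVA computation", {
  ses <- small_session()
  sc <- single_cell_snr(ses$tensor, seed = 1)
  expect_equal(nrow(sc), 40)
  # recompute the tuning-variance form for neuron 1 by hand
  X <- ses$tensor$values
  means <- apply(X[1, , ], 1, mean)
  within <- mean(apply(X[1, , ], 1, var))
  expect_equal(sc$snr_anova[1], var(means) / within, tolerance = 1e-12)
  expect_true(all(sc$snr_pairs >= 0, na.rm = TRUE))
  expect_false(any(sc$zero_within))
})

test_that("noise correlations decay with peak distance and shuffle flat", {
  cfg <- synth_config(n_neurons = 80, n_trials_per_direction = 60,
                      width_dist = list(kind = "uniform", min = 1, max = 2),
                      amp_dist = list(kind = "constant", value = 1),
                      indep_noise_var = 0.3,
                      limited_range = list(c = 0.5, lambda_d = 2),
                      differential_eps = 0, seed = 43)
  ses <- simulate_session(cfg)
  prof <- noise_correlation_profile(ses$tensor, ses$tuning, seed = 1)
  expect_gt(prof$mean_corr[prof$dist == 0], prof$mean_corr[prof$dist == 8])
  expect_gt(prof$mean_corr[prof$dist == 0], 0.1)
  shuf <- trial_shuffle(ses$tensor, seed = 2)
  prof_s <- noise_correlation_profile(shuf, ses$tuning, seed = 1)
  expect_lt(max(abs(prof_s$mean_corr), na.rm = TRUE), 0.05)
})
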