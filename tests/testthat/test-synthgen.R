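test_that("synth_config validates its inputs", {
  expect_s3_class(synth_config(seed = 1), "synth_config")
  expect_error(synth_config(indep_noise_var = -1), "indep_noise_var")
  expect_error(synth_config(differential_eps = -0.1), "differential_eps")
  expect_error(synth_config(limited_range = list(c = -1, lambda_d = 2)),
               "limited_range")
  expect_error(synth_config(width_dist = list(kind = "gamma")), "unknown")
  expect_error(synth_config(width_dist = list(kind = "uniform",
                                              min = 2, max = 1)),
               "uniform")
  expect_error(synth_config(amp_dist = list(kind = "constant", value = -1)),
               "constant")
})

test_that("lognormal varlog is converted to sdlog", {
  cfg <- synth_config(width_dist = list(kind = "lognormal", meanlog = 0,
                                        varlog = 4))
  expect_equal(cfg$width_dist$sdlog, 2)
})

test_that("place fields have the documented shapes", {
  cfg <- synth_config(n_neurons = 50, seed = 2)
  tun <- make_place_fields(cfg)
  expect_s3_class(tun, "population_tuning")
  expect_equal(dim(tun$means), c(50, 40))
  expect_equal(dim(tun$signal_vectors), c(50, 38))
  expect_equal(ncol(tun$signal_vectors), 2 * (cfg$n_bins - 1))
  # unit signal vectors have unit norm (or are all-zero placeholders)
  nrm <- colSums(tun$unit_signal^2)
  expect_true(all(abs(nrm - 1) < 1e-12 | nrm == 0))
  # signal vector = forward difference of the tuning matrix
  expect_equal(tun$signal_vectors[, 1], tun$means[, 2] - tun$means[, 1])
  expect_equal(tun$signal_vectors[, 20], tun$means[, 22] - tun$means[, 21])
})

test_that("place-field generation is deterministic in the seed", {
  cfg <- synth_config(n_neurons = 20, seed = 7)
  expect_equal(make_place_fields(cfg)$means, make_place_fields(cfg)$means)
})

test_that("zero-width fields collapse onto a single bin", {
  cfg <- synth_config(n_neurons = 5,
                      width_dist = list(kind = "constant", value = 0),
                      amp_dist = list(kind = "constant", value = 2),
                      seed = 3)
  tun <- make_place_fields(cfg, directions = 1L)
  expect_true(all(rowSums(tun$means > 0) == 1))
  expect_true(all(apply(tun$means, 1, max) == 2))
})

test_that("noise covariance assembles as the sum of its components", {
  cfg <- synth_config(n_neurons = 25, indep_noise_var = 0.3,
                      limited_range = list(c = 0.2, lambda_d = 2),
                      differential_eps = 0.4, seed = 5)
  tun <- make_place_fields(cfg)
  nm <- make_noise_covariance(tun, cfg, bin_pair = 4)
  with(nm$components,
       expect_equal(nm$covariance, D + C_LR + differential, tolerance = 1e-12))
  # diagonal part
  expect_equal(diag(nm$components$D), rep(0.3, 25))
  # differential part is rank one along the pair's signal vector
  dmu <- tun$signal_vectors[, 4]
  expect_equal(nm$components$differential, 0.4 * tcrossprod(dmu),
               tolerance = 1e-12)
  # limited-range part decays with peak distance
  K <- nm$components$C_LR
  pk <- tun$peak_positions[, 1]
  expect_equal(K[1, 2],
               0.2 * 0.3 * exp(-abs(pk[1] - pk[2]) / 2), tolerance = 1e-12)
  # positive semi-definite
  expect_gte(min(eigen(nm$covariance, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-10)
})

test_that("leftward bin pairs use the leftward signal vector", {
  cfg <- synth_config(n_neurons = 15, differential_eps = 1, seed = 6,
                      limited_range = list(c = 0, lambda_d = 2))
  tun <- make_place_fields(cfg)
  pair_left <- (cfg$n_bins - 1L) + 3L
  nm <- make_noise_covariance(tun, cfg, bin_pair = pair_left)
  expect_equal(nm$components$differential,
               tcrossprod(tun$signal_vectors[, pair_left]),
               tolerance = 1e-12)
  expect_error(make_noise_covariance(tun, cfg, bin_pair = 39), "out of range")
})

test_that("linear Fisher information matches the diagonal closed form", {
  cfg <- synth_config(n_neurons = 30, indep_noise_var = 0.5,
                      limited_range = list(c = 0, lambda_d = 2),
                      differential_eps = 0, seed = 8)
  tun <- make_place_fields(cfg)
  nm <- make_noise_covariance(tun, cfg, bin_pair = 10)
  dmu <- tun$signal_vectors[, 10]
  expect_equal(linear_fisher_info(tun, nm, 10), sum(dmu^2) / 0.5,
               tolerance = 1e-10)
})

test_that("information saturates at 1/eps under the differential model", {
  eps <- 0.05
  cfg <- synth_config(n_neurons = 400, indep_noise_var = 0.25,
                      limited_range = list(c = 0, lambda_d = 2),
                      differential_eps = eps, seed = 9)
  tun <- make_place_fields(cfg)
  nm <- make_noise_covariance(tun, cfg, bin_pair = 10)
  dmu <- tun$signal_vectors[, 10]
  I0 <- sum(dmu^2) / 0.25
  # Sherman-Morrison: I = I0 / (1 + eps I0)
  expect_equal(linear_fisher_info(tun, nm, 10), I0 / (1 + eps * I0),
               tolerance = 1e-8)
  expect_lt(linear_fisher_info(tun, nm, 10), 1 / eps)
})

test_that("sampled tensors are reproducible and converge to their targets", {
  cfg <- synth_config(n_neurons = 10, n_trials_per_direction = 2000,
                      indep_noise_var = 0.4,
                      limited_range = list(c = 0, lambda_d = 2),
                      differential_eps = 0, seed = 11)
  tun <- make_place_fields(cfg)
  Sigma <- diag(0.4, 10)
  t1 <- sample_activity_tensor(tun, Sigma, n_trials = 2000, seed = 1)
  t2 <- sample_activity_tensor(tun, Sigma, n_trials = 2000, seed = 1)
  expect_identical(t1$values, t2$values)
  s <- t(t1$values[, 3, ])
  # sample means sit within 4 standard errors of the generative means
  se <- sqrt(0.4 / 2000)
  expect_lt(max(abs(colMeans(s) - tun$means[, 3])), 4 * se)
  expect_equal(cov(s), Sigma, tolerance = 0.12)
})

test_that("simulate_session returns a coherent bundle", {
  ses <- small_session()
  expect_s3_class(ses$tensor, "activity_tensor")
  expect_equal(dim(ses$tensor), c(40, 40, 30))
  expect_length(ses$noise, 40)
  expect_s3_class(ses$noise[[1]], "noise_model")
})

test_that("simulated behavior obeys the track and speed design", {
  cfg <- synth_config(seed = 12)
  b <- make_behavior(cfg, n_runs = 6)
  expect_s3_class(b, "behavior_trace")
  expect_true(all(b$position >= 0 & b$position <= 120))
  expect_setequal(unique(b$direction), c(1L, 2L))
  # alternating directions: first run rightward
  expect_equal(b$direction[1], 1L)
  # no jitter: deterministic
  expect_identical(make_behavior(cfg, n_runs = 6)$position, b$position)
  # jitter is seed-reproducible and bounded to the track
  bj <- make_behavior(cfg, n_runs = 6, jitter_sd = 0.5, seed = 99)
  expect_identical(make_behavior(cfg, n_runs = 6, jitter_sd = 0.5,
                                 seed = 99)$position, bj$position)
  expect_true(all(bj$position >= 0 & bj$position <= 120))
})

test_that("fluorescence simulation produces spikes where tuning is high", {
  cfg <- synth_config(n_neurons = 8, seed = 13,
                      width_dist = list(kind = "constant", value = 1.5),
                      amp_dist = list(kind = "constant", value = 1))
  tun <- make_place_fields(cfg)
  b <- make_behavior(cfg, n_runs = 4)
  fl <- make_fluorescence(tun, b, seed = 5)
  expect_equal(dim(fl$fluor), c(length(b$position), 8))
  expect_equal(dim(fl$spikes), dim(fl$fluor))
  expect_true(all(fl$spikes >= 0))
  expect_gt(sum(fl$spikes), 0)
})
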