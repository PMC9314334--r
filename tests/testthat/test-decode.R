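test_that("the decoder builds one binary classifier per class pair", {
  ses <- small_session()
  halves <- split_trials(ses$tensor, seed = 1)
  model <- train_decoder(halves$train)
  expect_s3_class(model, "decoder_model")
  expect_equal(model$n_binary_classifiers, choose(40, 2))
  expect_equal(model$n_binary_classifiers, 780)
  expect_equal(model$classes, 0:39)
})

test_that("training requires at least 2 samples per class", {
  X <- array(rnorm(2 * 4 * 1), dim = c(2, 4, 1))
  tens <- activity_tensor(X, n_bins = 2, directions = 2, track_length = 12)
  expect_error(train_decoder(tens), "fewer than 2")
})

test_that("well-separated classes decode perfectly", {
  # 8 neurons, one strongly tuned to each of 8 classes; tiny noise
  set.seed(5)
  n_tr <- 12
  X <- array(rnorm(8 * 8 * n_tr, sd = 0.02), dim = c(8, 8, n_tr))
  for (k in 1:8) X[k, k, ] <- X[k, k, ] + 1
  tens <- activity_tensor(X, n_bins = 4, directions = 2, track_length = 24)
  halves <- split_trials(tens, seed = 2)
  model <- train_decoder(halves$train)
  ev <- evaluate_decoder(model, halves$test)
  expect_equal(ev$mse, 0)
  expect_equal(ev$rms, 0)
  expect_equal(ev$direction_errors, 0)
  expect_equal(sum(diag(ev$confusion)), ev$n_samples)
})

test_that("positional error is distance between bin centers, direction-free", {
  # class 0 (bin 0, right) vs class 25 (bin 5, left) on a 20-bin track:
  # centers 3 cm and 33 cm -> 30 cm error; direction error counted separately
  ses <- small_session()
  expect_equal(placecode:::class_center_cm(ses$tensor, 1), 3)
  expect_equal(placecode:::class_center_cm(ses$tensor, 26), 33)
  expect_equal(placecode:::class_direction(ses$tensor, 26), 2L)
  expect_equal(placecode:::class_bin(ses$tensor, 26), 5L)
})

test_that("saturation fit recovers exact parameters from a noiseless curve", {
  n <- c(10, 25, 50, 100, 200, 400)
  fit <- fit_saturation(data.frame(size = n, imse = 2 * n / (1 + n / 150)))
  expect_equal(fit$I0, 2, tolerance = 1e-6)
  expect_equal(fit$N, 150, tolerance = 1e-4)
  expect_equal(fit$asymptote, fit$I0 * fit$N, tolerance = 1e-6)
  expect_equal(fit$fitted(150), 2 * 150 / 2, tolerance = 1e-4)
})

test_that("saturation points are the documented multiples of N", {
  fit <- fit_saturation(data.frame(size = c(10, 50, 200),
                                   imse = 1 * c(10, 50, 200) /
                                     (1 + c(10, 50, 200) / 80)))
  expect_equal(fit$n_slope5, (sqrt(20) - 1) * fit$N)
  expect_equal(fit$n_asymp95, 19 * fit$N)
})

test_that("saturation fit rejects under-determined input", {
  expect_error(fit_saturation(data.frame(size = c(1, 2), imse = c(1, 2))),
               "at least 3")
})

test_that("aggregation takes geometric means within animals", {
  agg <- aggregate_saturation(c(100, 400, 900), c("a", "a", "b"))
  expect_equal(unname(agg$per_animal["a"]), 200)  # sqrt(100 * 400)
  expect_equal(unname(agg$per_animal["b"]), 900)
  expect_equal(agg$range, c(200, 900))
  expect_error(aggregate_saturation(c(-1, 2), c("a", "a")))
})

test_that("imse_curve is reproducible and returns one row per size", {
  ses <- small_session()
  c1 <- imse_curve(ses$tensor, sizes = c(10, 20), n_subsets = 3, seed = 9)
  c2 <- imse_curve(ses$tensor, sizes = c(10, 20), n_subsets = 3, seed = 9)
  expect_equal(c1, c2)
  expect_equal(c1$size, c(10, 20))
  expect_true(all(c1$imse > 0))
  expect_true(all(c1$n_used <= 3))
  expect_error(imse_curve(ses$tensor, sizes = 1000), "exceeds")
})

test_that("more neurons decode better on correlation-free data", {
  cfg <- synth_config(n_neurons = 60, n_trials_per_direction = 40,
                      width_dist = list(kind = "uniform", min = 1, max = 2),
                      amp_dist = list(kind = "constant", value = 1),
                      indep_noise_var = 0.6,
                      limited_range = list(c = 0, lambda_d = 2),
                      differential_eps = 0, seed = 31)
  ses <- simulate_session(cfg)
  cv <- imse_curve(ses$tensor, sizes = c(10, 60), n_subsets = 6, seed = 4)
  expect_gt(cv$imse[2], cv$imse[1])
})
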