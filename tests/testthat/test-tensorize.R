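test_that("position discretization covers 40 classes of 6 cm bins", {
  b <- list(position = c(0, 3, 119.9, 120), direction = c(1L, 1L, 1L, 2L),
            track_length = 120)
  disc <- discretize_position(b, 20)
  expect_equal(disc$bin, c(0L, 0L, 19L, 19L))
  expect_equal(disc$class, c(0L, 0L, 19L, 39L))
  expect_equal(disc$n_classes, 40L)
  expect_equal(disc$bin_length, 6)
  expect_error(discretize_position(list(position = -1, direction = 1L,
                                        track_length = 120)),
               "outside")
})

test_that("clean runs segment into valid trials, dips are rejected", {
  cfg <- synth_config(seed = 21)
  b <- make_behavior(cfg, n_runs = 10)
  seg <- segment_valid_trials(b)
  expect_s3_class(seg, "trial_segmentation")
  expect_equal(sum(seg$n_valid), 10)
  expect_equal(seg$n_valid, c(5L, 5L))
  # a mid-track dip below the 4 cm/s rule splits that run out
  b2 <- make_behavior(cfg, n_runs = 10, slow_runs = c(3, 8))
  seg2 <- segment_valid_trials(b2)
  expect_equal(sum(seg2$n_valid), 8)
  # per-frame labels agree with the trial table
  tr <- seg$trials
  for (r in seq_len(nrow(tr)))
    expect_true(all(seg$trial[tr$start[r]:tr$end[r]] == tr$id[r]))
})

test_that("every valid trial visits every bin", {
  cfg <- synth_config(seed = 22)
  b <- make_behavior(cfg, n_runs = 6)
  seg <- segment_valid_trials(b)
  disc <- discretize_position(b, 20)
  for (r in seq_len(nrow(seg$trials))) {
    idx <- seg$trials$start[r]:seg$trials$end[r]
    expect_length(unique(disc$bin[idx]), 20)
  }
})

test_that("tensor entries are the mean burst values of each bin visit", {
  cfg <- synth_config(seed = 23)
  b <- make_behavior(cfg, n_runs = 4)
  seg <- segment_valid_trials(b)
  burst <- cbind(seq_along(b$position) / 100,
                 sin(seq_along(b$position) / 50))
  tens <- build_activity_tensor(burst, b, seg)
  disc <- discretize_position(b, 20)
  # check one visit by hand: trial 1, its direction, bin 5 (class 4)
  tr <- seg$trials[1, ]
  idx <- tr$start:tr$end
  frames <- idx[disc$class[idx] == 4L]
  expect_equal(tens$values[1, 5, 1], mean(burst[frames, 1]))
  expect_equal(tens$values[2, 5, 1], mean(burst[frames, 2]))
  expect_equal(tens$visit_frames[1, 5, 1], length(frames))
  expect_equal(tens$trials_per_direction, c(2L, 2L))
})

test_that("trial shuffle preserves per-(neuron,bin) multisets exactly", {
  ses <- small_session()
  sh <- trial_shuffle(ses$tensor, seed = 1)
  X <- ses$tensor$values; Y <- sh$values
  for (k in c(1, 17, 40))
    for (n in c(1, 40))
      expect_equal(sort(Y[n, k, ]), sort(X[n, k, ]))
  # tuning (trial means) is exactly preserved
  expect_equal(apply(Y, c(1, 2), mean), apply(X, c(1, 2), mean),
               tolerance = 1e-12)
  # but the arrangement changed somewhere
  expect_false(identical(X, Y))
  # reproducible
  expect_identical(trial_shuffle(ses$tensor, seed = 1)$values, Y)
})

test_that("session tiers follow the inclusion thresholds", {
  expect_equal(filter_sessions(149, 40, 40), "excluded")
  expect_equal(filter_sessions(151, 29, 40), "excluded")
  expect_equal(filter_sessions(151, 31, 31), "working")
  expect_equal(filter_sessions(200, 30, 30), "large-data")
  expect_equal(filter_sessions(230, 35, 33), "large-data")
})

test_that("tracking noise is recovered from jittered behavior", {
  cfg <- synth_config(seed = 24)
  b <- make_behavior(cfg, n_runs = 40, jitter_sd = 0.5, seed = 7)
  seg <- segment_valid_trials(b)
  expect_gt(sum(seg$n_valid), 30)
  est <- estimate_tracking_noise(b, seg)
  expect_gt(est$scale, 0.35)
  expect_lt(est$scale, 0.65)
  expect_gt(est$n_residuals, 100)
})

test_that("trial splits are stratified, disjoint and exhaustive", {
  ses <- small_session()
  halves <- split_trials(ses$tensor, seed = 3)
  expect_equal(halves$train$trials_per_direction, c(15L, 15L))
  expect_equal(halves$test$trials_per_direction, c(15L, 15L))
  # every original trial's bin-1 value appears in exactly one half
  orig <- ses$tensor$values[1, 1, ]
  tr <- halves$train$values[1, 1, ]
  te <- halves$test$values[1, 1, ]
  expect_setequal(c(tr, te), orig)
  expect_length(intersect(tr, te), 0)
  expect_error(split_trials(ses$tensor, seed = 1, train_frac = 0.01),
               "degenerate")
})
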