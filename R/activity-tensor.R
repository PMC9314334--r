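#' Activity tensor: neurons x spatial-directional bins x trials
#'
#' The central container of the pipeline. Entry (n, k, t) holds neuron n's
#' mean event-trace value over the frames of trial t's visit to
#' spatial-directional bin k. Columns `1..n_bins` are the rightward bins,
#' `n_bins+1..2*n_bins` the leftward bins (for two-direction tensors).
#' Trial t of the rightward slice and trial t of the leftward slice are
#' different runs; when the two directions have unequal trial counts the
#' shorter one is padded with `NA`.
#'
#' @param values numeric array `[neurons, K, trials]`.
#' @param n_bins spatial bins per direction.
#' @param directions 1 or 2.
#' @param track_length cm.
#' @param trials_per_direction integer vector (length = directions) of valid
#'   trial counts.
#' @param visit_frames optional array like `values` holding the number of
#'   frames in each visit (effective integration time bookkeeping).
#' @return an `activity_tensor` object.
#' @export
activity_tensor <- function(values, n_bins, directions = 2L,
                            track_length = 120,
                            trials_per_direction = NULL,
                            visit_frames = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  K <- dim(values)[2]
  stopifnot(K == n_bins * directions)
  if (is.null(trials_per_direction))
    trials_per_direction <- rep(dim(values)[3], directions)
  structure(list(values = values,
                 n_bins = as.integer(n_bins),
                 directions = as.integer(directions),
                 track_length = track_length,
                 bin_length = track_length / n_bins,
                 trials_per_direction = as.integer(trials_per_direction),
                 visit_frames = visit_frames),
            class = "activity_tensor")
}

#' @export
print.activity_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("activity tensor: %d neurons x %d spatial-directional bins x %d trials\n",
              d[1], d[2], d[3]))
  cat(sprintf("  %d bins/direction, %.1f cm bins, trials/direction: %s\n",
              x$n_bins, x$bin_length,
              paste(x$trials_per_direction, collapse = "/")))
  invisible(x)
}

#' @export
dim.activity_tensor <- function(x) dim(x$values)

# direction index (1-based) of a spatial-directional class (1-based)
class_direction <- function(tensor, k) ((k - 1L) %/% tensor$n_bins) + 1L

# 0-based spatial bin of a class
class_bin <- function(tensor, k) (k - 1L) %% tensor$n_bins

# center (cm) of a class's spatial bin
class_center_cm <- function(tensor, k) {
  (class_bin(tensor, k) + 0.5) * tensor$bin_length
}

# trials x neurons matrix of the valid samples of one class
class_samples <- function(tensor, k) {
  m <- t(tensor$values[, k, , drop = TRUE])
  if (is.null(dim(m))) m <- matrix(m, ncol = dim(tensor$values)[1])
  ok <- stats::complete.cases(m)
  m[ok, , drop = FALSE]
}

#' Sample an activity tensor from tuning curves and a noise model
#'
#' Draws `X[, k, t] = f(, k) + eta`, with `eta` zero-mean Gaussian with the
#' bin's covariance, independent across trials. Pass one noise model per
#' spatial-directional bin (a list) or a single shared one. Noise is additive
#' on event-trace values; by default no floor is applied so that sample
#' covariances converge to their targets exactly. Set `floor = 0` for a
#' rectified (non-negative) variant.
#'
#' @param tuning a [make_place_fields()] result.
#' @param noise a `noise_model`, a covariance matrix, or a list of one per
#'   bin (length `K`).
#' @param n_trials trials per direction (>= 2).
#' @param seed integer seed.
#' @param floor optional clipping floor (default `NULL`, off).
#' @param track_length cm (default 120).
#' @return an [activity_tensor()].
#' @export
sample_activity_tensor <- function(tuning, noise, n_trials, seed,
                                   floor = NULL, track_length = 120) {
  stopifnot(inherits(tuning, "population_tuning"))
  if (n_trials < 2)
    stop("n_trials must be >= 2 (trial-to-trial variance undefined otherwise)")
  n <- nrow(tuning$means)
  K <- ncol(tuning$means)
  get_sigma <- function(k) {
    s <- if (is.list(noise) && !inherits(noise, "noise_model")) noise[[k]] else noise
    if (inherits(s, "noise_model")) s$covariance else s
  }
  set.seed(seed)
  X <- array(0, dim = c(n, K, n_trials))
  for (k in seq_len(K)) {
    Sigma <- get_sigma(k)
    if (all(Sigma == 0)) {
      eta <- matrix(0, n_trials, n)
    } else {
      eta <- MASS::mvrnorm(n_trials, mu = rep(0, n), Sigma = Sigma)
      if (n_trials == 1) eta <- matrix(eta, nrow = 1)
    }
    X[, k, ] <- tuning$means[, k] + t(eta)
  }
  if (!is.null(floor)) X[X < floor] <- floor
  activity_tensor(X, n_bins = tuning$n_bins, directions = tuning$directions,
                  track_length = track_length)
}

#' Simulate a complete synthetic session
#'
#' Convenience wrapper: draws place fields, assembles one noise covariance per
#' spatial-directional bin (shared independent and limited-range parts, local
#' differential part), and samples the activity tensor. The ground truth is
#' returned alongside so that every downstream estimator can be validated.
#'
#' @param config a [synth_config()].
#' @param floor see [sample_activity_tensor()].
#' @return list with `tensor`, `tuning`, `noise` (list of `noise_model`, one
#'   per bin; the bin's model is the one of its forward adjacent pair, the
#'   last bin of each direction reusing the preceding pair), and `config`.
#' @examples
#' ses <- simulate_session(synth_config(n_neurons = 30,
#'                                      n_trials_per_direction = 20, seed = 4))
#' dim(ses$tensor)
#' @export
simulate_session <- function(config, floor = NULL) {
  tuning <- make_place_fields(config)
  B <- config$n_bins
  noise <- vector("list", 2L * B)
  for (d in 1:2) {
    for (b in seq_len(B)) {
      pair <- (d - 1L) * (B - 1L) + min(b, B - 1L)  # forward pair; last bin reuses it
      noise[[(d - 1L) * B + b]] <-
        make_noise_covariance(tuning, config, bin_pair = pair)
    }
  }
  tensor <- sample_activity_tensor(tuning, noise,
                                   n_trials = config$n_trials_per_direction,
                                   seed = config$seed + 1L,
                                   floor = floor,
                                   track_length = config$track_length)
  list(tensor = tensor, tuning = tuning, noise = noise, config = config)
}
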