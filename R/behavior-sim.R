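#' Simulate linear-track running behavior
#'
#' Generates alternating end-to-end runs with a trapezoidal speed profile
#' (accelerate, cruise, decelerate), mimicking a mouse shuttling between the
#' two reward ends of a linear track. Speed at the turnarounds stays above
#' the validity floor (4 cm/s) by default; selected runs can be given a
#' mid-track slow dip (to exercise valid-trial rejection) or a curved
#' deviation from uniform motion (to exercise the robust tracking-noise
#' estimator). Optional Gaussian jitter emulates camera tracking noise.
#'
#' @param config a [synth_config()] (track length / frame rate are used).
#' @param n_runs number of runs (directions alternate, first rightward).
#' @param cruise_speed cruise speed cm/s (default 20).
#' @param accel acceleration magnitude cm/s^2 (default 40).
#' @param turn_speed speed at the track ends, cm/s (default 6; must stay
#'   above the 4 cm/s validity floor for clean runs).
#' @param slow_runs integer indices of runs that pause to `dip_speed`
#'   mid-track for `dip_duration` seconds.
#' @param dip_speed cm/s during a dip (default 2, below the 4 cm/s rule).
#' @param dip_duration seconds (default 1).
#' @param curved_runs integer indices of runs whose mid-track motion deviates
#'   sinusoidally from the uniform-motion line by up to `curve_amp` cm, with
#'   `curve_cycles` oscillations per run under a smooth taper that pins the
#'   run ends.
#' @param curve_amp cm (default 4).
#' @param curve_cycles oscillations per curved run (default 2; with the
#'   default cruise speed, more cycles can push the apparent speed below the
#'   validity floor and the run is rejected rather than contaminating).
#' @param jitter_sd tracking-noise standard deviation, cm (default 0).
#' @param seed integer seed (jitter only; the profile is deterministic).
#' @return a `behavior_trace`: `time` (s), `position` (cm), `direction`
#'   (1 = rightward, 2 = leftward, per frame), `frame_rate`, `track_length`.
#' @export
make_behavior <- function(config, n_runs = 20,
                          cruise_speed = 20, accel = 40, turn_speed = 6,
                          slow_runs = integer(0), dip_speed = 2,
                          dip_duration = 1,
                          curved_runs = integer(0), curve_amp = 4,
                          curve_cycles = 2, jitter_sd = 0,
                          seed = config$seed) {
  stopifnot(inherits(config, "synth_config"), n_runs >= 1)
  if (turn_speed <= 0) stop("turn_speed must be > 0")
  L <- config$track_length
  fr <- config$frame_rate
  dt <- 1 / fr
  pos <- numeric(0)
  dir <- integer(0)
  for (run in seq_len(n_runs)) {
    going_right <- run %% 2L == 1L
    x <- if (going_right) 0 else L
    run_pos <- numeric(0)
    dipping <- 0L
    repeat {
      travelled <- if (going_right) x else L - x
      remaining <- L - travelled
      if (remaining <= 0) break
      v_acc <- turn_speed + accel * (length(run_pos)) * dt
      v_dec <- sqrt(turn_speed^2 + 2 * accel * remaining)
      v <- min(cruise_speed, v_acc, v_dec)
      if (run %in% slow_runs && dipping == 0L && travelled >= L / 2)
        dipping <- as.integer(round(dip_duration * fr))
      if (dipping > 0L) {
        v <- dip_speed
        dipping <- dipping - 1L
      }
      x <- x + (if (going_right) v else -v) * dt
      x <- min(max(x, 0), L)
      run_pos <- c(run_pos, x)
      if (length(run_pos) > 100 * fr) break  # safety cap
    }
    if (run %in% curved_runs) {
      frac <- seq_along(run_pos) / (length(run_pos) + 1)
      run_pos <- run_pos + curve_amp * sin(2 * pi * curve_cycles * frac) *
        sin(pi * frac)^2
      run_pos <- pmin(pmax(run_pos, 0), L)
    }
    pos <- c(pos, run_pos)
    dir <- c(dir, rep(if (going_right) 1L else 2L, length(run_pos)))
  }
  if (jitter_sd > 0) {
    set.seed(seed)
    pos <- pmin(pmax(pos + stats::rnorm(length(pos), 0, jitter_sd), 0), L)
  }
  structure(list(time = (seq_along(pos) - 1) * dt,
                 position = pos,
                 direction = dir,
                 frame_rate = fr,
                 track_length = L),
            class = "behavior_trace")
}

#' @export
print.behavior_trace <- function(x, ...) {
  cat(sprintf("behavior trace: %d frames (%.1f s at %g Hz), track %.0f cm\n",
              length(x$position), max(x$time), x$frame_rate, x$track_length))
  invisible(x)
}

#' Simulate fluorescence traces from tuning and behavior
#'
#' Draws Poisson spikes with position-dependent rates proportional to the
#' tuning curves, convolves them with a double-exponential calcium-indicator
#' kernel, and adds white measurement noise. This is the generative front end
#' for testing the event detector and the full
#' behavior-to-tensor pipeline.
#'
#' @param tuning a [make_place_fields()] result.
#' @param behavior a [make_behavior()] result.
#' @param kinetics `list(rise =, decay =, noise_sd =)` in seconds / dF/F
#'   units (defaults 0.1 s, 0.5 s, 0.1).
#' @param rate_scale peak firing rate (Hz) for a unit-amplitude field
#'   (default 5).
#' @param spike_amp dF/F amplitude of one spike's transient (default 0.5).
#' @param seed integer seed.
#' @return list with `fluor` (frames x neurons matrix), `spikes` (same
#'   shape, counts), and `kernel`.
#' @export
make_fluorescence <- function(tuning, behavior,
                              kinetics = list(rise = 0.1, decay = 0.5,
                                              noise_sd = 0.1),
                              rate_scale = 5, spike_amp = 0.5,
                              seed = 1L) {
  stopifnot(inherits(tuning, "population_tuning"),
            inherits(behavior, "behavior_trace"))
  if (kinetics$rise <= 0 || kinetics$decay <= 0)
    stop("kinetics rise/decay must be positive")
  fr <- behavior$frame_rate
  disc <- discretize_position(behavior, n_bins = tuning$n_bins)
  cls <- disc$class + 1L  # 1-based column of the tuning matrix
  n <- nrow(tuning$means)
  n_frames <- length(cls)
  tk <- seq(0, 6 * kinetics$decay, by = 1 / fr)
  kern <- (1 - exp(-tk / kinetics$rise)) * exp(-tk / kinetics$decay)
  if (max(kern) > 0) kern <- kern / max(kern)
  set.seed(seed)
  rates <- tuning$means[, cls, drop = FALSE] * rate_scale / fr  # n x frames
  spikes <- matrix(stats::rpois(n * n_frames, lambda = pmax(rates, 0)),
                   nrow = n)
  fluor <- matrix(0, n_frames, n)
  for (i in seq_len(n)) {
    conv <- stats::convolve(spikes[i, ] * spike_amp, rev(kern),
                            type = "open")[seq_len(n_frames)]
    fluor[, i] <- conv +
      if (kinetics$noise_sd > 0)
        stats::rnorm(n_frames, 0, kinetics$noise_sd) else 0
  }
  list(fluor = fluor, spikes = t(spikes), kernel = kern)
}

#' Simulate behavior plus fluorescence in one call
#'
#' @inheritParams make_fluorescence
#' @param config a [synth_config()].
#' @param n_runs runs to simulate.
#' @param ... further arguments passed to [make_behavior()].
#' @return list with `behavior` and the [make_fluorescence()] fields.
#' @export
make_behavior_and_fluorescence <- function(config, tuning,
                                           kinetics = list(rise = 0.1,
                                                           decay = 0.5,
                                                           noise_sd = 0.1),
                                           n_runs = 20, ...) {
  behavior <- make_behavior(config, n_runs = n_runs, ...)
  fl <- make_fluorescence(tuning, behavior, kinetics = kinetics,
                          seed = config$seed + 2L)
  c(list(behavior = behavior), fl)
}
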