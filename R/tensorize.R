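#' Discretize track positions into spatial-directional bins
#'
#' Positions are binned into `n_bins` half-open intervals
#' \eqn{[k L/n_{bins}, (k+1) L/n_{bins})} per running direction, the last bin
#' closed so that position = L falls in bin `n_bins - 1`. Bin indices are
#' 0-based; the spatial-directional class is
#' `direction * n_bins + bin` (rightward = 0, leftward = 1), giving
#' `2 * n_bins` classes — 40 for the default 20-bin track.
#'
#' @param behavior a [make_behavior()] result (or a list with `position`,
#'   `direction`, `track_length`).
#' @param n_bins bins per direction (default 20).
#' @return list: `bin` (0-based spatial bin per frame), `class` (0-based
#'   spatial-directional class), `n_bins`, `n_classes`, `bin_length` (cm).
#' @examples
#' b <- list(position = c(3, 120), direction = c(1L, 1L), track_length = 120)
#' discretize_position(b, 20)$bin   # 0 and 19
#' @export
discretize_position <- function(behavior, n_bins = 20) {
  pos <- behavior$position
  L <- behavior$track_length
  if (any(pos < 0 | pos > L))
    stop("positions outside [0, track_length]")
  bin <- pmin(floor(pos / (L / n_bins)), n_bins - 1L)
  dir0 <- behavior$direction - 1L
  list(bin = as.integer(bin),
       class = as.integer(dir0 * n_bins + bin),
       n_bins = as.integer(n_bins),
       n_classes = 2L * as.integer(n_bins),
       bin_length = L / n_bins)
}

#' Segment behavior into valid running trials
#'
#' A valid trial is a maximal contiguous single-direction segment in which
#' the running speed always exceeds `min_speed` (4 cm/s by default) and
#' every spatial bin on the track is visited.
#'
#' @param behavior a [make_behavior()] result.
#' @param min_speed cm/s floor (default 4; must be positive).
#' @param n_bins bins per direction for the coverage rule (default 20).
#' @param speed_halfwin half-window (frames) of the centered difference used
#'   to estimate running speed (default 5, i.e. 0.5 s at 20 Hz). Averaging
#'   keeps camera tracking jitter from masquerading as speed changes; set to
#'   1 for raw frame-to-frame speed.
#' @return a `trial_segmentation`: `trial` (per-frame trial id, `NA` outside
#'   valid trials), `trials` (data.frame: id, direction, start, end,
#'   n_frames), `n_valid` (length-2 count per direction).
#' @export
segment_valid_trials <- function(behavior, min_speed = 4, n_bins = 20,
                                 speed_halfwin = 5L) {
  if (min_speed <= 0) stop("min_speed must be > 0")
  pos <- behavior$position
  n <- length(pos)
  fr <- behavior$frame_rate
  i <- seq_len(n)
  lo <- pmax(i - speed_halfwin, 1L)
  hi <- pmin(i + speed_halfwin, n)
  speed <- abs(pos[hi] - pos[lo]) * fr / pmax(hi - lo, 1L)
  ok <- speed > min_speed
  seg_id <- cumsum(c(TRUE, diff(behavior$direction) != 0 | diff(ok) != 0))
  trial <- rep(NA_integer_, n)
  rows <- list()
  next_id <- 0L
  disc <- discretize_position(behavior, n_bins)
  for (s in unique(seg_id)) {
    idx <- which(seg_id == s)
    if (!all(ok[idx])) next
    if (length(unique(disc$bin[idx])) < n_bins) next  # must visit every bin
    next_id <- next_id + 1L
    trial[idx] <- next_id
    rows[[next_id]] <- data.frame(id = next_id,
                                  direction = behavior$direction[idx[1]],
                                  start = idx[1], end = idx[length(idx)],
                                  n_frames = length(idx))
  }
  trials <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), direction = integer(0), start = integer(0),
               end = integer(0), n_frames = integer(0))
  structure(list(trial = trial, trials = trials,
                 n_valid = c(sum(trials$direction == 1L),
                             sum(trials$direction == 2L))),
            class = "trial_segmentation")
}

#' Build the activity tensor from burst traces and behavior
#'
#' Entry (n, k, t) is the arithmetic mean of neuron n's burst-trace values
#' over the frames of valid trial t's visit to spatial-directional bin k.
#' Visit frame counts are retained (effective integration time varies with
#' running speed). Trials that miss a bin are excluded upstream by
#' [segment_valid_trials()]; an unvisited bin here is an assertion failure.
#'
#' @param burst frames x neurons matrix of burst traces.
#' @param behavior a [make_behavior()] result aligned frame-by-frame.
#' @param segmentation a [segment_valid_trials()] result.
#' @param n_bins bins per direction (default 20).
#' @return an [activity_tensor()] (directions with fewer trials NA-padded).
#' @export
build_activity_tensor <- function(burst, behavior, segmentation,
                                  n_bins = 20) {
  stopifnot(is.matrix(burst), nrow(burst) == length(behavior$position))
  disc <- discretize_position(behavior, n_bins)
  trials <- segmentation$trials
  n_neurons <- ncol(burst)
  K <- 2L * n_bins
  Tmax <- max(segmentation$n_valid, 1L)
  X <- array(NA_real_, dim = c(n_neurons, K, Tmax))
  Fcnt <- array(NA_real_, dim = c(n_neurons, K, Tmax))
  t_of_dir <- c(0L, 0L)
  for (r in seq_len(nrow(trials))) {
    d <- trials$direction[r]
    t_of_dir[d] <- t_of_dir[d] + 1L
    idx <- trials$start[r]:trials$end[r]
    cls <- disc$class[idx] + 1L
    for (k in unique(cls)) {
      fr <- idx[cls == k]
      X[, k, t_of_dir[d]] <- colMeans(burst[fr, , drop = FALSE])
      Fcnt[, k, t_of_dir[d]] <- length(fr)
    }
    covered <- sort(unique(disc$bin[idx]))
    if (length(covered) < n_bins)
      stop("internal: valid trial with an unvisited bin")
  }
  activity_tensor(X, n_bins = n_bins, directions = 2L,
                  track_length = behavior$track_length,
                  trials_per_direction = t_of_dir,
                  visit_frames = Fcnt)
}

#' Trial-shuffle an activity tensor
#'
#' Randomly permutes each neuron's activity values across trials, within the
#' same spatial-directional bin, independently per (neuron, bin). This
#' removes noise correlations while preserving every neuron's tuning
#' exactly: the per-(neuron, bin) multiset of values — hence the trial mean
#' and variance — is unchanged. Apply separately to training and testing
#' partitions when decoding.
#'
#' @param tensor an [activity_tensor()].
#' @param seed integer seed.
#' @return the shuffled [activity_tensor()].
#' @export
trial_shuffle <- function(tensor, seed) {
  stopifnot(inherits(tensor, "activity_tensor"))
  X <- tensor$values
  d <- dim(X)
  if (d[3] < 2) {
    warning("single trial: shuffle is the identity")
    return(tensor)
  }
  set.seed(seed)
  for (k in seq_len(d[2])) {
    valid <- which(apply(!is.na(X[, k, , drop = FALSE]), 3, all))
    if (length(valid) < 2) next
    for (n in seq_len(d[1]))
      X[n, k, valid] <- X[n, k, valid[sample.int(length(valid))]]
  }
  out <- tensor
  out$values <- X
  out
}

#' Session quality-control tier
#'
#' Classifies a session by the inclusion thresholds: "working" sessions
#' surpass 150 identified neurons (strict) and have at least 30 valid trials
#' in each direction; "large-data" sessions additionally have at least 200
#' neurons; anything else is "excluded".
#'
#' @param n_neurons identified neuron count.
#' @param n_trials_right,n_trials_left valid trial counts per direction.
#' @return one of "excluded", "working", "large-data".
#' @examples
#' filter_sessions(149, 40, 40)  # excluded
#' filter_sessions(151, 31, 31)  # working
#' filter_sessions(230, 35, 33)  # large-data
#' @export
filter_sessions <- function(n_neurons, n_trials_right, n_trials_left) {
  working <- n_neurons > 150 && n_trials_right >= 30 && n_trials_left >= 30
  if (!working) return("excluded")
  if (n_neurons >= 200) "large-data" else "working"
}

#' Robust estimate of position-tracking noise
#'
#' For each valid trial, takes the frames in the center of the track (spatial
#' bins 7 to 13 of 20, where motion is near-uniform), fits a time-position
#' line on half of those frames (even-numbered frames within the trial) and
#' collects residuals on the other half, then pools residuals over trials
#' and reports the robust scale IQR/1.349 — the interquartile range
#' normalized to match a Gaussian standard deviation. Each held-out residual
#' is divided by \eqn{\sqrt{1 + h_0}}, where \eqn{h_0} is the prediction
#' leverage of its frame under the fitted line, so that the scale estimates
#' the noise standard deviation without the finite-sample inflation of
#' out-of-sample prediction error.
#'
#' @param behavior a [make_behavior()] result.
#' @param segmentation a [segment_valid_trials()] result.
#' @param center_bins 0-based spatial bins treated as center track
#'   (default `7:13`).
#' @param n_bins bins per direction (default 20).
#' @return list: `scale` (cm, robust), `sd` (plain standard deviation, for
#'   comparison), `n_residuals`, `n_trials_used`.
#' @export
estimate_tracking_noise <- function(behavior, segmentation,
                                    center_bins = 7:13, n_bins = 20) {
  trials <- segmentation$trials
  if (nrow(trials) < 1) stop("need at least one valid trial")
  disc <- discretize_position(behavior, n_bins)
  resids <- numeric(0)
  used <- 0L
  for (r in seq_len(nrow(trials))) {
    idx <- trials$start[r]:trials$end[r]
    ctr <- idx[disc$bin[idx] %in% center_bins]
    if (length(ctr) < 6) next
    fit_idx <- ctr[seq_along(ctr) %% 2L == 0L]
    test_idx <- ctr[seq_along(ctr) %% 2L == 1L]
    if (length(fit_idx) < 2 || length(test_idx) < 1) next
    Xf <- cbind(1, behavior$time[fit_idx])
    fit <- stats::lm.fit(Xf, behavior$position[fit_idx])
    Xt <- cbind(1, behavior$time[test_idx])
    pred <- Xt %*% fit$coefficients
    XtXinv <- chol2inv(chol(crossprod(Xf)))
    lev <- rowSums((Xt %*% XtXinv) * Xt)
    r <- (behavior$position[test_idx] - drop(pred)) / sqrt(1 + lev)
    resids <- c(resids, r)
    used <- used + 1L
  }
  if (used == 0L) stop("no trial had enough center-track frames")
  list(scale = unname(stats::IQR(resids, type = 7) / 1.349),
       sd = stats::sd(resids),
       n_residuals = length(resids),
       n_trials_used = used)
}

#' Stratified random split of trials into training and testing halves
#'
#' Randomly selects 50% of the valid trials per direction as the training
#' set, the rest as the held-out test set.
#'
#' @param tensor an [activity_tensor()].
#' @param seed integer seed.
#' @param train_frac training fraction (default 0.5).
#' @return list of two [activity_tensor()]s: `train` and `test`.
#' @export
split_trials <- function(tensor, seed, train_frac = 0.5) {
  stopifnot(inherits(tensor, "activity_tensor"))
  set.seed(seed)
  d <- dim(tensor$values)
  B <- tensor$n_bins
  tr_idx <- list(); te_idx <- list()
  for (dd in seq_len(tensor$directions)) {
    Td <- tensor$trials_per_direction[dd]
    n_tr <- floor(Td * train_frac)
    if (n_tr < 1 || Td - n_tr < 1)
      stop("degenerate split: too few trials in direction ", dd)
    tr <- sort(sample.int(Td, n_tr))
    tr_idx[[dd]] <- tr
    te_idx[[dd]] <- setdiff(seq_len(Td), tr)
  }
  take <- function(which_idx) {
    Tm <- max(vapply(which_idx, length, 1L))
    X <- array(NA_real_, dim = c(d[1], d[2], Tm))
    for (dd in seq_len(tensor$directions)) {
      cols <- (dd - 1L) * B + seq_len(B)
      sel <- which_idx[[dd]]
      X[, cols, seq_along(sel)] <- tensor$values[, cols, sel]
    }
    activity_tensor(X, n_bins = B, directions = tensor$directions,
                    track_length = tensor$track_length,
                    trials_per_direction = vapply(which_idx, length, 1L))
  }
  list(train = take(tr_idx), test = take(te_idx))
}
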