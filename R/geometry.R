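# Noise-covariance eigenmode geometry: SNR along principal noise
# directions, cos^2 overlap with the signal direction, and the PLS
# visualization embedding.

#' Eigenmodes of a bin's noise covariance
#'
#' The mean-subtracted trial vectors of one spatial-directional bin are the
#' noise samples; their sample covariance is eigendecomposed and the modes
#' sorted by decreasing eigenvalue. At most trials - 1 eigenvalues can be
#' strictly positive. Eigenvector signs are fixed deterministically (the
#' largest-magnitude coordinate is made positive) so downstream reports are
#' reproducible; cos^2 overlaps are sign-free anyway.
#'
#' @param tensor an [activity_tensor()].
#' @param k 1-based spatial-directional class index.
#' @param neurons optional neuron subset.
#' @return a `noise_eigenmodes`: `Sigma`, `values` (descending), `vectors`
#'   (orthonormal columns), `n_trials`, `rank_bound`.
#' @export
noise_eigenmodes <- function(tensor, k, neurons = NULL) {
  m <- class_samples(tensor, k)
  if (!is.null(neurons)) m <- m[, neurons, drop = FALSE]
  if (nrow(m) < 3) stop("need at least 3 trials in the bin")
  Sigma <- stats::cov(m)
  ev <- eigen(Sigma, symmetric = TRUE)
  V <- ev$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(Sigma = Sigma, values = ev$values, vectors = V,
                 n_trials = nrow(m), rank_bound = nrow(m) - 1L),
            class = "noise_eigenmodes")
}

#' @export
print.noise_eigenmodes <- function(x, ...) {
  cat(sprintf("noise eigenmodes: %d neurons, %d trials (rank bound %d)\n",
              nrow(x$Sigma), x$n_trials, x$rank_bound))
  cat("  top eigenvalues:", signif(utils::head(x$values, 5), 4), "\n")
  invisible(x)
}

#' SNR along each principal noise direction
#'
#' Estimates the noise covariance eigenvectors \eqn{PC_{k,train}} from the
#' training half (pooled over the pair's two bins), projects both the
#' training and the held-out testing half onto each mode, and computes the
#' 1-D signal \eqn{(PC^T \Delta\mu)^2}, noise (pooled projected variance)
#' and their ratio per mode. The train-set projection overestimates the SNR
#' relative to the cross-validated test-set projection; both are returned.
#'
#' @param tensor an [activity_tensor()].
#' @param pair adjacent-bin pair index (see [signal_direction()]).
#' @param seed split seed.
#' @param neurons optional neuron subset.
#' @param n_modes number of leading modes to report (default: all).
#' @return data.frame per mode: `mode`, `eigenvalue`, `signal_test`,
#'   `noise_test`, `snr_test`, `snr_train`.
#' @export
snr_along_modes <- function(tensor, pair, seed = 1L, neurons = NULL,
                            n_modes = NULL) {
  halves <- split_trials(tensor, seed)
  ks <- pair_classes(tensor, pair)
  get2 <- function(tens) {
    s1 <- class_samples(tens, ks[1]); s2 <- class_samples(tens, ks[2])
    if (!is.null(neurons)) {
      s1 <- s1[, neurons, drop = FALSE]; s2 <- s2[, neurons, drop = FALSE]
    }
    list(s1 = s1, s2 = s2)
  }
  tr <- get2(halves$train); te <- get2(halves$test)
  ctr <- function(m) sweep(m, 2, colMeans(m))
  pooled <- rbind(ctr(tr$s1), ctr(tr$s2))
  Sigma_tr <- crossprod(pooled) / (nrow(pooled) - 2)
  ev <- eigen(Sigma_tr, symmetric = TRUE)
  V <- ev$vectors
  if (is.null(n_modes)) n_modes <- ncol(V)
  n_modes <- min(n_modes, ncol(V))
  one_side <- function(side) {
    dmu <- colMeans(side$s2) - colMeans(side$s1)
    p1 <- side$s1 %*% V; p2 <- side$s2 %*% V
    sig <- drop(crossprod(V, dmu))^2
    noi <- ((nrow(p1) - 1) * apply(p1, 2, stats::var) +
              (nrow(p2) - 1) * apply(p2, 2, stats::var)) /
      (nrow(p1) + nrow(p2) - 2)
    list(sig = sig, noi = noi)
  }
  tr_q <- one_side(tr); te_q <- one_side(te)
  idx <- seq_len(n_modes)
  data.frame(mode = idx,
             eigenvalue = ev$values[idx],
             signal_test = te_q$sig[idx],
             noise_test = te_q$noi[idx],
             snr_test = ifelse(te_q$noi[idx] > 0,
                               te_q$sig[idx] / te_q$noi[idx], NA_real_),
             snr_train = ifelse(tr_q$noi[idx] > 0,
                                tr_q$sig[idx] / tr_q$noi[idx], NA_real_))
}

#' Ground-truth SNR decomposition along noise eigenmodes
#'
#' For a known signal vector and noise covariance, the per-mode SNR is
#' \eqn{(PC_k^T \Delta\mu)^2 / \lambda_k}; summed over a complete basis it
#' equals \eqn{\Delta\mu^T \Sigma^{-1} \Delta\mu}, the SNR along the
#' direction maximizing SNR (the linear Fisher information).
#'
#' @param dmu signal vector.
#' @param Sigma noise covariance (full rank).
#' @return data.frame: `mode`, `eigenvalue`, `snr`.
#' @export
snr_modes_true <- function(dmu, Sigma) {
  ev <- eigen(Sigma, symmetric = TRUE)
  proj2 <- drop(crossprod(ev$vectors, dmu))^2
  data.frame(mode = seq_along(ev$values),
             eigenvalue = ev$values,
             snr = proj2 / ev$values)
}

#' Overlap between noise eigenmodes and the signal direction
#'
#' For each noise direction, the squared cosine of its angle with the unit
#' signal vector; the total overlap sums the first `n_modes` squared
#' cosines (six by default). Over a complete orthonormal basis the squared
#' cosines sum to 1.
#'
#' @param modes a [noise_eigenmodes()] result (or an orthonormal-column
#'   matrix).
#' @param unit_signal unit signal vector (normalized with a warning if not).
#' @param n_modes modes entering the total (default 6, capped at the number
#'   available).
#' @return list: `cos2` (per mode), `total` (first `n_modes`), `n_modes`.
#' @export
signal_noise_overlap <- function(modes, unit_signal, n_modes = 6) {
  V <- if (inherits(modes, "noise_eigenmodes")) modes$vectors else modes
  nrm <- sqrt(sum(unit_signal^2))
  if (abs(nrm - 1) > 1e-8) {
    warning("signal vector not unit length; normalizing")
    unit_signal <- unit_signal / nrm
  }
  cos2 <- drop(crossprod(V, unit_signal))^2
  n_modes <- min(n_modes, length(cos2))
  list(cos2 = cos2, total = sum(cos2[seq_len(n_modes)]), n_modes = n_modes)
}

#' Shuffle-referenced change in signal-noise overlap
#'
#' Computes the total overlap (first `n_modes` squared cosines between the
#' noise eigenmodes and the signal direction) for the unmodified tensor and
#' for its trial-shuffled version, averaged over adjacent-bin pairs, and
#' returns the difference. Noise correlations aligned with the signal make
#' this difference positive; it shrinks toward zero as the shuffle leaves
#' nothing to remove.
#'
#' @param tensor an [activity_tensor()].
#' @param seed shuffle seed.
#' @param n_modes modes in the total (default 6).
#' @param pairs pair indices to average over (default: all).
#' @return list: `delta` (unmodified minus shuffled, mean over pairs),
#'   `total_unmodified`, `total_shuffled`.
#' @export
overlap_difference <- function(tensor, seed = 1L, n_modes = 6,
                               pairs = NULL) {
  n_pairs <- (tensor$n_bins - 1L) * tensor$directions
  if (is.null(pairs)) pairs <- seq_len(n_pairs)
  shuf <- trial_shuffle(tensor, seed)
  tot_u <- tot_s <- numeric(length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[i]
    ks <- pair_classes(tensor, p)
    u <- signal_direction(tensor, p)$unit
    tot_u[i] <- signal_noise_overlap(noise_eigenmodes(tensor, ks[1]),
                                     u, n_modes)$total
    us <- signal_direction(shuf, p)$unit
    tot_s[i] <- signal_noise_overlap(noise_eigenmodes(shuf, ks[1]),
                                     us, n_modes)$total
  }
  list(delta = mean(tot_u - tot_s),
       total_unmodified = mean(tot_u),
       total_shuffled = mean(tot_s))
}

#' PLS embedding of the population activity for visualization
#'
#' Partial least squares regression of the z-scored trial-bin population
#' vectors on the z-scored behavioral targets (spatial position and running
#' direction), via NIPALS with deflation of the predictor block. The
#' components maximize covariance between neural responses and behavior and
#' are used for visualization only (not cross-validated).
#'
#' @param tensor an [activity_tensor()].
#' @param n_components components to extract (default 2).
#' @return list: `scores` (samples x components), `loadings`, `class`
#'   (0-based spatial-directional class per sample), `position` (bin),
#'   `direction`, `dropped` (constant neuron columns removed before
#'   z-scoring).
#' @export
pls_embed <- function(tensor, n_components = 2) {
  K <- dim(tensor$values)[2]
  xs <- list(); cls <- integer(0)
  for (k in seq_len(K)) {
    m <- class_samples(tensor, k)
    if (nrow(m) == 0) next
    xs[[length(xs) + 1L]] <- m
    cls <- c(cls, rep(k - 1L, nrow(m)))
  }
  if (length(unique(cls)) < 2) stop("need at least 2 populated classes")
  X <- do.call(rbind, xs)
  keep <- apply(X, 2, stats::sd) > 0
  if (any(!keep))
    warning(sum(!keep), " constant neuron column(s) dropped before z-scoring")
  X <- scale(X[, keep, drop = FALSE])
  bin <- cls %% tensor$n_bins
  dir <- cls %/% tensor$n_bins
  Y <- scale(cbind(position = bin, direction = dir))
  if (any(!is.finite(Y))) Y <- Y[, apply(is.finite(Y), 2, all), drop = FALSE]
  W <- matrix(0, ncol(X), n_components)
  S <- matrix(0, nrow(X), n_components)
  Xd <- X
  for (c_i in seq_len(n_components)) {
    M <- crossprod(Xd, Y)          # p x q cross-covariance
    sv <- svd(M, nu = 1, nv = 0)
    w <- sv$u[, 1]
    t_sc <- Xd %*% w
    p_load <- crossprod(Xd, t_sc) / drop(crossprod(t_sc))
    Xd <- Xd - t_sc %*% t(p_load)
    W[, c_i] <- w
    S[, c_i] <- t_sc
  }
  list(scores = S, loadings = W, class = cls,
       position = bin, direction = dir, dropped = which(!keep))
}
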