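#' Assemble the trial-to-trial noise covariance for one bin pair
#'
#' Builds \eqn{\Sigma = D + cK + \varepsilon \Delta\mu \Delta\mu^T} where
#' `D = diag(indep_noise_var)`,
#' \eqn{K_{ij} = \sqrt{D_{ii} D_{jj}} \exp(-d_{ij}/\lambda_d)} with
#' \eqn{d_{ij}} the linear distance in bins between the two neurons' PF
#' peaks (no wraparound: the track is linear), and the differential term uses
#' the *local* signal vector of the requested adjacent-bin pair, so that the
#' noise component parallel to the signal direction limits information there.
#'
#' If the assembled matrix is numerically indefinite, negative eigenvalues
#' are clipped at zero (with a warning) to restore positive semi-definiteness.
#'
#' @param tuning a [make_place_fields()] result.
#' @param config the matching [synth_config()].
#' @param bin_pair adjacent-bin pair index (1-based column of
#'   `tuning$signal_vectors`); pairs `1..n_bins-1` belong to the rightward
#'   block, the next `n_bins-1` to the leftward block.
#' @return an object of class `noise_model`: `covariance` (neurons x neurons),
#'   `components` (list `D`, `C_LR`, `differential`), `bin_pair`, and
#'   `psd_repaired` flag.
#' @examples
#' cfg <- synth_config(n_neurons = 20, seed = 3)
#' tun <- make_place_fields(cfg)
#' nm <- make_noise_covariance(tun, cfg, bin_pair = 5)
#' all(eigen(nm$covariance, symmetric = TRUE, only.values = TRUE)$values > -1e-10)
#' @export
make_noise_covariance <- function(tuning, config, bin_pair) {
  stopifnot(inherits(tuning, "population_tuning"),
            inherits(config, "synth_config"))
  n <- nrow(tuning$means)
  if (n != config$n_neurons)
    stop("tuning and config disagree on the neuron count")
  n_pairs <- ncol(tuning$signal_vectors)
  if (bin_pair < 1 || bin_pair > n_pairs)
    stop("bin_pair out of range 1..", n_pairs)
  d_idx <- if (bin_pair <= tuning$n_bins - 1L || tuning$directions == 1L) 1L else 2L
  Dv <- rep(config$indep_noise_var, n)
  D <- diag(Dv, n)
  c_lr <- config$limited_range$c
  if (c_lr > 0) {
    pk <- tuning$peak_positions[, d_idx]
    dist <- abs(outer(pk, pk, "-"))
    K <- sqrt(outer(Dv, Dv)) * exp(-dist / config$limited_range$lambda_d)
    diag(K) <- Dv
    C_LR <- c_lr * K
  } else {
    C_LR <- matrix(0, n, n)
  }
  dmu <- tuning$signal_vectors[, bin_pair]
  Diff <- config$differential_eps * tcrossprod(dmu)
  Sigma <- D + C_LR + Diff
  rep_flag <- FALSE
  ev <- eigen(Sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-10 * max(abs(ev$values))) {
    warning("assembled covariance indefinite; clipping negative eigenvalues at 0")
    lam <- pmax(ev$values, 0)
    Sigma <- ev$vectors %*% (lam * t(ev$vectors))
    Sigma <- (Sigma + t(Sigma)) / 2
    rep_flag <- TRUE
  }
  structure(list(covariance = Sigma,
                 components = list(D = D, C_LR = C_LR, differential = Diff),
                 bin_pair = bin_pair,
                 psd_repaired = rep_flag),
            class = "noise_model")
}

#' Linear Fisher information for one adjacent-bin pair
#'
#' Computes \eqn{I = \Delta\mu^T \Sigma^{-1} \Delta\mu}, the linear Fisher
#' information about position carried by the population across the given
#' adjacent-bin pair, with the discrete signal vector \eqn{\Delta\mu}
#' standing in for the tuning-curve derivative f'. Units are 1/(bin
#' spacing)^2; divide by the squared bin length to express it per cm^2.
#'
#' With a purely differential covariance \eqn{\Sigma = D + \varepsilon
#' \Delta\mu\Delta\mu^T}, the Sherman-Morrison identity gives
#' \eqn{I = I_0 / (1 + \varepsilon I_0)} with
#' \eqn{I_0 = \Delta\mu^T D^{-1} \Delta\mu}: information saturates at
#' \eqn{1/\varepsilon} however many neurons are added.
#'
#' @param tuning a [make_place_fields()] result (or any object with a
#'   `signal_vectors` matrix).
#' @param noise a [make_noise_covariance()] result, or a covariance matrix.
#' @param bin_pair adjacent-bin pair index.
#' @param pseudoinverse if `TRUE`, use the Moore-Penrose pseudoinverse when
#'   the covariance is singular; otherwise singularity is an error.
#' @return Fisher information (scalar, 1/bins^2).
#' @export
linear_fisher_info <- function(tuning, noise, bin_pair, pseudoinverse = FALSE) {
  Sigma <- if (inherits(noise, "noise_model")) noise$covariance else noise
  dmu <- tuning$signal_vectors[, bin_pair]
  stopifnot(length(dmu) == nrow(Sigma))
  sol <- tryCatch(solve(Sigma, dmu), error = function(e) NULL)
  if (is.null(sol)) {
    if (!pseudoinverse)
      stop("covariance is singular; set pseudoinverse = TRUE to use ginv")
    sol <- MASS::ginv(Sigma) %*% dmu
  }
  drop(crossprod(dmu, sol))
}
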