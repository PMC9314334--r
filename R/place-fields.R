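#' Generate Gaussian place fields for a synthetic population
#'
#' Creates Gaussian-like receptive fields located randomly within the track,
#' evaluated at bin centers. Each neuron gets a peak position drawn uniformly
#' over the track, a half-width drawn from `config$width_dist`, and a peak
#' amplitude drawn from `config$amp_dist`. With `directions = 2`, fields are
#' drawn independently per running direction (directional place fields), and
#' the tuning matrix has `2 * n_bins` spatial-directional columns
#' (rightward block first).
#'
#' The local signal vector for adjacent-bin pair p (bins p, p+1 within one
#' direction) is \eqn{\Delta\mu_p = f(\cdot, p+1) - f(\cdot, p)}, the discrete
#' proxy for the tuning-curve derivative f'; its unit version is the signal
#' direction.
#'
#' @param config a [synth_config()].
#' @param directions 1 or 2 running directions (default 2).
#' @return an object of class `population_tuning` with elements
#'   `means` (neurons x K matrix, K = directions * n_bins),
#'   `peak_positions` (neurons x directions, continuous bin units),
#'   `peak_bins` (bin index of maximum, 0-based, per direction),
#'   `widths`, `amplitudes`, `n_bins`, `directions`,
#'   `signal_vectors` (neurons x pairs matrix; `n_bins - 1` adjacent pairs
#'   per direction), and `unit_signal` (columnwise-normalized signal vectors).
#' @examples
#' tun <- make_place_fields(synth_config(n_neurons = 50, seed = 2))
#' dim(tun$means)          # 50 x 40
#' ncol(tun$signal_vectors)  # 19 pairs per direction
#' @export
make_place_fields <- function(config, directions = 2L) {
  stopifnot(inherits(config, "synth_config"), directions %in% c(1L, 2L))
  set.seed(config$seed)
  n <- config$n_neurons
  B <- config$n_bins
  widths <- draw_dist(config$width_dist, n)
  amps <- draw_dist(config$amp_dist, n)
  centers <- seq_len(B) - 0.5          # bin centers in bin units
  peak_pos <- matrix(stats::runif(n * directions, min = 0, max = B),
                     nrow = n, ncol = directions)
  means <- matrix(0, n, directions * B)
  for (d in seq_len(directions)) {
    dist2 <- outer(peak_pos[, d], centers, function(p, c) (p - c)^2)
    block <- amps * exp(-dist2 / (2 * widths^2))
    # width -> 0 limit: activity collapses onto the peak's own bin
    degenerate <- widths < 1e-12
    if (any(degenerate)) {
      block[degenerate, ] <- 0
      pk <- pmin(floor(peak_pos[degenerate, d]), B - 1) + 1
      block[cbind(which(degenerate), pk)] <- amps[degenerate]
    }
    means[, (d - 1) * B + seq_len(B)] <- block
  }
  peak_bins <- matrix(0L, n, directions)
  for (d in seq_len(directions)) {
    blk <- means[, (d - 1) * B + seq_len(B), drop = FALSE]
    peak_bins[, d] <- max.col(blk, ties.method = "first") - 1L
  }
  out <- list(means = means,
              peak_positions = peak_pos,
              peak_bins = peak_bins,
              widths = widths,
              amplitudes = amps,
              n_bins = B,
              directions = as.integer(directions))
  sv <- tuning_signal_vectors(out)
  out$signal_vectors <- sv$dmu
  out$unit_signal <- sv$unit
  class(out) <- "population_tuning"
  out
}

# Adjacent-bin signal vectors within each direction block.
tuning_signal_vectors <- function(tuning) {
  B <- tuning$n_bins
  pairs_per_dir <- B - 1L
  n_pairs <- pairs_per_dir * tuning$directions
  dmu <- matrix(0, nrow(tuning$means), n_pairs)
  j <- 0L
  for (d in seq_len(tuning$directions)) {
    off <- (d - 1L) * B
    for (p in seq_len(pairs_per_dir)) {
      j <- j + 1L
      dmu[, j] <- tuning$means[, off + p + 1L] - tuning$means[, off + p]
    }
  }
  nrm <- sqrt(colSums(dmu^2))
  unit <- sweep(dmu, 2, ifelse(nrm > 0, nrm, 1), "/")
  list(dmu = dmu, unit = unit)
}

#' @export
print.population_tuning <- function(x, ...) {
  cat(sprintf("population tuning: %d neurons, %d bins x %d direction(s)\n",
              nrow(x$means), x$n_bins, x$directions))
  cat(sprintf("  widths (bins): median %.2f [%.2f, %.2f]\n",
              stats::median(x$widths), min(x$widths), max(x$widths)))
  invisible(x)
}
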