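#' Configuration for a synthetic linear-track session
#'
#' Bundles every parameter of the synthetic-session generator: track geometry,
#' place-field (PF) width and amplitude distributions, and the three noise
#' covariance components (independent, limited-range, differential). The
#' defaults emulate the recording conditions of the study this package
#' models: a 120 cm linear track discretized into 20 bins of ~6 cm per
#' running direction, imaged at 20 Hz.
#'
#' The trial-to-trial noise covariance for spatial-directional bin k is
#' assembled as
#' \deqn{\Sigma_k = D + c\,K + \varepsilon\,\Delta\mu_k \Delta\mu_k^T}
#' where \eqn{D} is diagonal (independent noise),
#' \eqn{K_{ij} = \sqrt{D_{ii}D_{jj}} e^{-d_{ij}/\lambda_d}} decays with the
#' distance \eqn{d_{ij}} between PF peaks (limited-range correlations), and
#' the rank-one differential term is aligned with the local signal vector
#' \eqn{\Delta\mu_k} so that it limits linear Fisher information at
#' \eqn{1/\varepsilon} no matter how many neurons are observed.
#'
#' @param n_neurons number of simulated neurons.
#' @param n_bins spatial bins per running direction (default 20).
#' @param track_length track length in cm (default 120).
#' @param n_trials_per_direction number of runs per direction.
#' @param width_dist PF half-width distribution, in bins. Either
#'   `list(kind = "lognormal", meanlog =, varlog =)` (log-normal in log(bins))
#'   or `list(kind = "uniform", min =, max =)`.
#' @param amp_dist PF peak-amplitude distribution:
#'   `list(kind = "constant", value =)` or
#'   `list(kind = "lognormal", meanlog =, sdlog =)`.
#' @param indep_noise_var per-neuron independent noise variance (event-trace
#'   units squared). The default 0.25, with unit-scale amplitudes, puts the
#'   single-cell between-bin/within-bin variance ratio near the ~0.4 observed
#'   for CA1 event traces.
#' @param limited_range `list(c =, lambda_d =)`: strength \eqn{c \ge 0} and
#'   length scale \eqn{\lambda_d} (bins) of the limited-range component.
#' @param differential_eps strength \eqn{\varepsilon \ge 0} of the
#'   information-limiting differential component.
#' @param frame_rate imaging frame rate in Hz (default 20).
#' @param seed integer seed making every generator call deterministic.
#'
#' @return an object of class `synth_config`.
#' @examples
#' cfg <- synth_config(n_neurons = 50, n_trials_per_direction = 30, seed = 1)
#' cfg$track_length / cfg$n_bins  # bin length in cm
#' @export
synth_config <- function(n_neurons = 200,
                         n_bins = 20,
                         track_length = 120,
                         n_trials_per_direction = 60,
                         width_dist = list(kind = "lognormal",
                                           meanlog = 0, varlog = 0.3),
                         amp_dist = list(kind = "lognormal",
                                         meanlog = 0, sdlog = 0.5),
                         indep_noise_var = 0.25,
                         limited_range = list(c = 0.2, lambda_d = 2),
                         differential_eps = 0.1,
                         frame_rate = 20,
                         seed = 1L) {
  stopifnot(n_neurons >= 1, n_bins >= 2, track_length > 0,
            n_trials_per_direction >= 1, frame_rate > 0)
  if (indep_noise_var < 0)
    stop("indep_noise_var must be >= 0")
  if (limited_range$c < 0 || limited_range$lambda_d <= 0)
    stop("limited_range: need strength c >= 0 and lambda_d > 0")
  if (differential_eps < 0)
    stop("differential_eps must be >= 0")
  width_dist <- validate_dist(width_dist, "width_dist")
  amp_dist <- validate_dist(amp_dist, "amp_dist")
  out <- list(n_neurons = as.integer(n_neurons),
              n_bins = as.integer(n_bins),
              track_length = track_length,
              n_trials_per_direction = as.integer(n_trials_per_direction),
              width_dist = width_dist,
              amp_dist = amp_dist,
              indep_noise_var = indep_noise_var,
              limited_range = limited_range,
              differential_eps = differential_eps,
              frame_rate = frame_rate,
              seed = as.integer(seed))
  class(out) <- "synth_config"
  out
}

validate_dist <- function(d, what) {
  if (!is.list(d) || is.null(d$kind))
    stop(what, " must be a list with a 'kind' field")
  switch(d$kind,
    lognormal = {
      if (!is.null(d$varlog)) {
        if (d$varlog < 0) stop(what, ": lognormal variance must be >= 0")
        d$sdlog <- sqrt(d$varlog)
      }
      if (is.null(d$sdlog) || d$sdlog < 0)
        stop(what, ": lognormal needs meanlog and sdlog (or varlog) >= 0")
      if (is.null(d$meanlog)) stop(what, ": lognormal needs meanlog")
    },
    uniform = {
      if (is.null(d$min) || is.null(d$max) || d$min > d$max || d$min <= 0)
        stop(what, ": uniform needs 0 < min <= max")
    },
    constant = {
      if (is.null(d$value) || d$value < 0)
        stop(what, ": constant needs value >= 0")
    },
    stop(what, ": unknown distribution kind '", d$kind, "'")
  )
  d
}

draw_dist <- function(d, n) {
  switch(d$kind,
    lognormal = stats::rlnorm(n, meanlog = d$meanlog, sdlog = d$sdlog),
    uniform   = stats::runif(n, min = d$min, max = d$max),
    constant  = rep(d$value, n))
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synthetic session config:\n")
  cat(sprintf("  %d neurons, %d bins/direction, %.0f cm track (%.1f cm bins)\n",
              x$n_neurons, x$n_bins, x$track_length,
              x$track_length / x$n_bins))
  cat(sprintf("  %d trials/direction, %g Hz, seed %d\n",
              x$n_trials_per_direction, x$frame_rate, x$seed))
  cat(sprintf("  widths: %s; amplitudes: %s\n",
              x$width_dist$kind, x$amp_dist$kind))
  cat(sprintf("  noise: indep var %.3g, limited-range c=%.3g lambda=%.3g, eps=%.3g\n",
              x$indep_noise_var, x$limited_range$c, x$limited_range$lambda_d,
              x$differential_eps))
  invisible(x)
}
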