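#' Alpha kernel for burst convolution
#'
#' Taps of \eqn{\alpha(t) = (t/\tau)\exp(1 - t/\tau)} sampled at the frame
#' rate from `t_min` to `t_max`. With the defaults (\eqn{\tau} = 0.2 s at
#' 20 Hz, t = 0.05..1.5 s) this yields 30 taps, and the analytic maximum
#' \eqn{\alpha(\tau) = 1} lies on the sampling grid.
#'
#' @param tau time constant, s (default 0.2).
#' @param frame_rate Hz (default 20).
#' @param t_min,t_max kernel support, s (defaults 0.05 and 1.5).
#' @return an `alpha_kernel` object: `taps`, `times`, `tau`, `frame_rate`.
#' @examples
#' k <- alpha_kernel()
#' length(k$taps)  # 30
#' max(k$taps)     # 1 (t = tau on the grid)
#' @export
alpha_kernel <- function(tau = 0.2, frame_rate = 20,
                         t_min = 0.05, t_max = 1.5) {
  stopifnot(tau > 0, frame_rate > 0, t_min > 0, t_max > t_min)
  times <- seq(t_min, t_max, by = 1 / frame_rate)
  taps <- (times / tau) * exp(1 - times / tau)
  structure(list(taps = taps, times = times, tau = tau,
                 frame_rate = frame_rate),
            class = "alpha_kernel")
}

#' Wavelet denoising and detection thresholds for a fluorescence trace
#'
#' First stage of the event detector: symlet-4 wavelet denoising with a
#' universal soft threshold (decomposition level `floor(log2(n))` capped at
#' 5), recovery of the removed noise component, and the two detection
#' thresholds derived from it — the minimum event size (three times the
#' noise standard deviation) and the minimum event peak value (first
#' quartile of the denoised trace plus the minimum event size). The first
#' quartile uses linear interpolation between order statistics
#' (`quantile(type = 7)`).
#'
#' @param trace numeric dF/F trace, or a list with `values`.
#' @return list: `denoised`, `noise` (trace minus denoised; additive by
#'   construction), `noise_sd`, `min_event_size`, `min_peak`, and a
#'   `degenerate` flag (`TRUE` when the noise scale is zero and thresholding
#'   degenerates, e.g. an all-constant trace).
#' @export
denoise_and_noise_floor <- function(trace) {
  x <- if (is.list(trace)) trace$values else trace
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (stats::sd(x) == 0) {
    # all-constant trace: nothing to denoise, thresholding degenerates
    den <- x
  } else {
    den <- wavelet_denoise(x)
  }
  noise <- x - den
  noise_sd <- stats::sd(noise)
  if (!is.finite(noise_sd)) noise_sd <- 0
  mes <- 3 * noise_sd
  mpk <- unname(stats::quantile(den, 0.25, type = 7)) + mes
  list(denoised = den, noise = noise, noise_sd = noise_sd,
       min_event_size = mes, min_peak = mpk,
       degenerate = noise_sd <= .Machine$double.eps)
}

# interior local maxima (endpoints are never extrema)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

local_minima <- function(x) local_maxima(-x)

#' Detect calcium events in a fluorescence trace
#'
#' Implements the threshold-free event detection algorithm: wavelet-denoise
#' the trace, find local maxima of the denoised trace above the minimum peak
#' value, pair each with the preceding local minimum (its baseline), set the
#' onset to the first frame between baseline and peak where the denoised
#' trace exceeds the baseline by the minimum event size, and discard events
#' whose peak rises less than the minimum event size above baseline. Peaks
#' with no preceding local minimum (trace edges) are dropped. Each
#' qualifying local maximum is treated as its own event, even when
#' consecutive peaks share a baseline.
#'
#' All thresholds scale with the trace, so multiplying a trace by a positive
#' constant leaves the detected event set unchanged.
#'
#' @param trace numeric dF/F trace.
#' @param thresholds optional precomputed [denoise_and_noise_floor()] result.
#' @return an `event_trace`: `raw_events` (zeros except event-onset frames,
#'   value = peak minus baseline), `onsets`, `peaks`, `amplitudes`,
#'   `thresholds`.
#' @export
detect_events <- function(trace, thresholds = NULL) {
  x <- if (is.list(trace)) trace$values else trace
  if (is.null(thresholds)) thresholds <- denoise_and_noise_floor(x)
  den <- thresholds$denoised
  raw <- numeric(length(x))
  onsets <- integer(0); peaks <- integer(0); amps <- numeric(0)
  if (thresholds$degenerate) {
    warning("degenerate noise floor; no events detected")
  } else {
    pk_idx <- local_maxima(den)
    pk_idx <- pk_idx[den[pk_idx] > thresholds$min_peak]
    mn_idx <- local_minima(den)
    for (p in pk_idx) {
      prev <- mn_idx[mn_idx < p]
      if (length(prev) == 0) next   # no baseline before an edge peak
      b <- max(prev)
      amp <- den[p] - den[b]
      if (amp < thresholds$min_event_size) next
      seg <- den[b:p]
      on_rel <- which(seg > den[b] + thresholds$min_event_size)[1]
      if (is.na(on_rel)) next
      onset <- b + on_rel - 1L
      raw[onset] <- raw[onset] + amp
      onsets <- c(onsets, onset); peaks <- c(peaks, p); amps <- c(amps, amp)
    }
  }
  structure(list(raw_events = raw, onsets = onsets, peaks = peaks,
                 amplitudes = amps, thresholds = thresholds),
            class = "event_trace")
}

#' Convolve an event trace with the alpha kernel and standardize
#'
#' Causal convolution of the raw event trace with the alpha function
#' (simulating a spike burst from each calcium event), truncated to the
#' trace length, then divided by its own standard deviation so every
#' neuron's burst trace has unit scale. A zero input passes through as zero
#' (no division).
#'
#' @param raw_events numeric vector (or an `event_trace`).
#' @param kernel an [alpha_kernel()].
#' @return numeric burst trace, same length as the input.
#' @export
burst_convolve <- function(raw_events, kernel = alpha_kernel()) {
  x <- if (inherits(raw_events, "event_trace")) raw_events$raw_events
       else raw_events
  stopifnot(inherits(kernel, "alpha_kernel"))
  n <- length(x)
  # direct sparse convolution: exact zeros before the first event
  # (FFT-based convolution leaves ~1e-17 residue on causally-silent frames)
  taps <- kernel$taps
  out <- numeric(n)
  for (j in which(x != 0)) {
    kmax <- min(n, j + length(taps) - 1L)
    out[j:kmax] <- out[j:kmax] + x[j] * taps[seq_len(kmax - j + 1L)]
  }
  s <- stats::sd(out)
  if (is.finite(s) && s > 0) out <- out / s
  out
}

#' Run the full event pipeline over a matrix of traces
#'
#' @param fluor frames x neurons matrix of dF/F traces.
#' @param kernel an [alpha_kernel()].
#' @return frames x neurons matrix of standardized burst traces.
#' @export
burst_traces <- function(fluor, kernel = alpha_kernel()) {
  stopifnot(is.matrix(fluor))
  apply(fluor, 2, function(x) burst_convolve(detect_events(x), kernel))
}
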