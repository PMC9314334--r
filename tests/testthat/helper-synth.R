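# Shared small fixtures, built once per test run.

# A compact two-direction session with known ground truth.
small_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_neurons = 40, n_trials_per_direction = 30,
                          width_dist = list(kind = "uniform",
                                            min = 1, max = 2.5),
                          amp_dist = list(kind = "constant", value = 1),
                          indep_noise_var = 0.2,
                          limited_range = list(c = 0.1, lambda_d = 2),
                          differential_eps = 0.3, seed = 42L)
      cache <<- simulate_session(cfg)
    }
    cache
  }
})

# Deterministic hand-built tensor: 2 neurons, 2 bins x 2 directions,
# 4 trials, every value distinct and known.
tiny_tensor <- function() {
  X <- array(0, dim = c(2, 4, 4))
  base <- array(seq_len(2 * 4 * 4), dim = c(2, 4, 4))
  X[] <- base / 10
  activity_tensor(X, n_bins = 2, directions = 2, track_length = 12)
}

# Fluorescence trace with transients of known onsets at a given SNR
# (peak amplitude / noise sd).
make_transient_trace <- function(n_frames = 2400, frame_rate = 20,
                                 onsets = seq(100, 2300, by = 200),
                                 snr = 6, noise_sd = 0.05, seed = 1L,
                                 decay = 0.4, rise = 0.07) {
  set.seed(seed)
  tt <- seq(0, 3, by = 1 / frame_rate)
  kern <- (1 - exp(-tt / rise)) * exp(-tt / decay)
  kern <- kern / max(kern)
  x <- numeric(n_frames)
  for (o in onsets) {
    idx <- o:min(o + length(kern) - 1L, n_frames)
    x[idx] <- x[idx] + snr * noise_sd * kern[seq_along(idx)]
  }
  list(trace = x + rnorm(n_frames, 0, noise_sd), clean = x,
       onsets = onsets, frame_rate = frame_rate, noise_sd = noise_sd)
}
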