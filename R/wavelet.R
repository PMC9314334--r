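# Decimated orthonormal wavelet transform (sym4) with periodic boundaries,
# used for trace denoising. Implemented here because the detector needs only
# this one transform: symlet-4 analysis/synthesis with universal soft
# thresholding (VisuShrink).

# Symlet-4 orthonormal decomposition filters.
SYM4_LO <- c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
             0.80373875180591614, 0.29785779560527736, -0.09921954357684722,
             -0.01260396726203783, 0.03222310060404270)
SYM4_HI <- c(-0.03222310060404270, -0.01260396726203783, 0.09921954357684722,
             0.29785779560527736, -0.80373875180591614, 0.49761866763201545,
             0.02963552764599851, -0.07576571478927333)

# One analysis step: x (even length) -> list(approx, detail), periodic.
dwt_step <- function(x) {
  N <- length(x)
  half <- N / 2L
  L <- length(SYM4_LO)
  idx <- outer(2 * seq_len(half) - 1, 0:(L - 1), "-") %% N + 1L
  xm <- matrix(x[idx], nrow = half)
  list(approx = drop(xm %*% SYM4_LO), detail = drop(xm %*% SYM4_HI))
}

# One synthesis step (inverse of dwt_step).
idwt_step <- function(approx, detail) {
  half <- length(approx)
  N <- 2L * half
  uV <- numeric(N); uW <- numeric(N)
  uV[2 * seq_len(half)] <- approx   # slot 2t+1 (0-based) = index 2t+2 (1-based)
  uW[2 * seq_len(half)] <- detail
  L <- length(SYM4_LO)
  out <- numeric(N)
  for (l in 0:(L - 1)) {
    sh <- c(uV[(l %% N + 1):N], uV[seq_len(l %% N)])
    shW <- c(uW[(l %% N + 1):N], uW[seq_len(l %% N)])
    out <- out + SYM4_LO[l + 1] * sh + SYM4_HI[l + 1] * shW
  }
  out
}

# Multi-level periodic DWT after reflection-padding to a multiple of 2^levels.
# The universal threshold sigma*sqrt(2 log n) is applied as a hard rule by
# default: hard thresholding is unbiased above the threshold, so calcium
# transient peaks keep their amplitude and the downstream 3-sigma event-size
# rule sees the true peak height. Soft thresholding (available via `rule`)
# shrinks every retained coefficient by the threshold, which visibly
# flattens transients.
wavelet_denoise <- function(x, levels = NULL, rule = c("hard", "soft")) {
  rule <- match.arg(rule)
  n <- length(x)
  if (n < 16) return(x)
  if (is.null(levels)) levels <- min(floor(log2(n)), 5L)
  block <- 2^levels
  n_pad <- ceiling(n / block) * block
  if (n_pad > n) {
    pad <- rev(x)[seq_len(min(n_pad - n, n))]
    if (length(pad) < n_pad - n)
      pad <- c(pad, rep(pad[length(pad)], n_pad - n - length(pad)))
    xp <- c(x, pad)
  } else xp <- x
  details <- vector("list", levels)
  approx <- xp
  for (j in seq_len(levels)) {
    st <- dwt_step(approx)
    details[[j]] <- st$detail
    approx <- st$approx
  }
  # noise scale from the finest detail coefficients; universal threshold
  sigma <- stats::median(abs(details[[1]])) / 0.6745
  thr <- sigma * sqrt(2 * log(length(xp)))
  shrink <- if (rule == "hard") function(w) w * (abs(w) > thr)
            else function(w) sign(w) * pmax(abs(w) - thr, 0)
  for (j in seq_len(levels)) details[[j]] <- shrink(details[[j]])
  for (j in rev(seq_len(levels))) approx <- idwt_step(approx, details[[j]])
  approx[seq_len(n)]
}
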