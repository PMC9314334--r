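# Cross-validated signal / noise / SNR estimators in the 1-D subspace
# spanned by the local signal direction.

# classes (1-based) of adjacent-bin pair j: pairs 1..B-1 are rightward,
# B..2(B-1) leftward
pair_classes <- function(tensor, pair) {
  B <- tensor$n_bins
  ppd <- B - 1L
  n_pairs <- ppd * tensor$directions
  if (pair < 1 || pair > n_pairs)
    stop("pair out of range 1..", n_pairs)
  d <- (pair - 1L) %/% ppd
  b <- (pair - 1L) %% ppd + 1L
  k1 <- d * B + b
  c(k1, k1 + 1L)
}

class_mean <- function(tensor, k, neurons = NULL) {
  m <- class_samples(tensor, k)
  if (!is.null(neurons)) m <- m[, neurons, drop = FALSE]
  if (nrow(m) < 2) stop("class ", k - 1L, " has fewer than 2 trials")
  colMeans(m)
}

#' Signal direction between two adjacent spatial bins
#'
#' The signal vector \eqn{\Delta\mu} points from the trial-averaged
#' population vector of one spatial bin to the adjacent one; its unit
#' version is the signal direction, the discrete proxy for the
#' tuning-curve derivative. A 20-bin track has 19 adjacent pairs per
#' running direction.
#'
#' @param tensor_train training [activity_tensor()].
#' @param pair adjacent-bin pair index (1-based; pairs `1..n_bins-1`
#'   rightward, the rest leftward).
#' @param neurons optional neuron subset.
#' @return list: `dmu`, `unit` (`dmu / |dmu|`), `norm`.
#' @export
signal_direction <- function(tensor_train, pair, neurons = NULL) {
  ks <- pair_classes(tensor_train, pair)
  dmu <- class_mean(tensor_train, ks[2], neurons) -
    class_mean(tensor_train, ks[1], neurons)
  nrm <- sqrt(sum(dmu^2))
  if (nrm == 0) stop("zero signal vector: direction undefined")
  list(dmu = dmu, unit = dmu / nrm, norm = nrm)
}

# core cross-validated estimate for an arbitrary class pair
cv_pair <- function(train, test, k1, k2, neurons = NULL,
                    printed_variant = FALSE) {
  m1_tr <- class_mean(train, k1, neurons)
  m2_tr <- class_mean(train, k2, neurons)
  dmu_tr <- m2_tr - m1_tr
  nrm <- sqrt(sum(dmu_tr^2))
  if (nrm == 0) stop("zero training signal vector")
  u_tr <- dmu_tr / nrm
  s1 <- class_samples(test, k1); s2 <- class_samples(test, k2)
  if (!is.null(neurons)) {
    s1 <- s1[, neurons, drop = FALSE]; s2 <- s2[, neurons, drop = FALSE]
  }
  if (nrow(s1) < 2 || nrow(s2) < 2) stop("degenerate split: too few test trials")
  dmu_te <- colMeans(s2) - colMeans(s1)
  signal <- drop(crossprod(u_tr, dmu_te))^2
  p1 <- drop(s1 %*% u_tr); p2 <- drop(s2 %*% u_tr)
  if (printed_variant) {
    # the printed formula mixes train and test unit vectors
    nrm_te <- sqrt(sum(dmu_te^2))
    u_te <- if (nrm_te > 0) dmu_te / nrm_te else u_tr
    q1 <- drop(s1 %*% u_te); q2 <- drop(s2 %*% u_te)
    noise <- ((nrow(s1) - 1) * stats::cov(p1, q1) +
                (nrow(s2) - 1) * stats::cov(p2, q2)) /
      (nrow(s1) + nrow(s2) - 2)
  } else {
    noise <- ((nrow(s1) - 1) * stats::var(p1) +
                (nrow(s2) - 1) * stats::var(p2)) /
      (nrow(s1) + nrow(s2) - 2)
  }
  c(signal = signal, noise = noise,
    snr = if (noise > 0) signal / noise else NA_real_)
}

#' Cross-validated signal, noise and SNR for one adjacent-bin pair
#'
#' Half the trials define the signal direction
#' \eqn{\hat{\Delta\mu}_{train}}; on the held-out half, the signal quantity
#' is \eqn{(\hat{\Delta\mu}_{train}^T \Delta\mu_{test})^2} and the noise
#' quantity is the trial-count-weighted pooled variance of both bins' test
#' samples projected onto \eqn{\hat{\Delta\mu}_{train}} (the quadratic form
#' \eqn{\hat{\Delta\mu}_{train}^T \Sigma_{test} \hat{\Delta\mu}_{train}}).
#' `printed_variant = TRUE` computes the train/test-mixed bilinear form
#' instead.
#'
#' @param tensor an [activity_tensor()].
#' @param pair adjacent-bin pair index.
#' @param seed split seed.
#' @param neurons optional neuron subset.
#' @param printed_variant see above (default `FALSE`).
#' @return named vector: `signal`, `noise`, `snr`.
#' @export
cv_signal_noise <- function(tensor, pair, seed = 1L, neurons = NULL,
                            printed_variant = FALSE) {
  halves <- split_trials(tensor, seed)
  ks <- pair_classes(tensor, pair)
  cv_pair(halves$train, halves$test, ks[1], ks[2], neurons,
          printed_variant)
}

#' Signal and noise for the direction-of-motion variable
#'
#' Same estimators as [cv_signal_noise()], but the pair is the two bins with
#' the same spatial position and opposite running directions.
#'
#' @param tensor an [activity_tensor()].
#' @param position_bin 0-based spatial bin.
#' @param seed split seed.
#' @param neurons optional neuron subset.
#' @return named vector: `signal`, `noise`, `snr`.
#' @export
motion_direction_snr <- function(tensor, position_bin, seed = 1L,
                                 neurons = NULL) {
  B <- tensor$n_bins
  stopifnot(position_bin >= 0, position_bin < B, tensor$directions == 2L)
  halves <- split_trials(tensor, seed)
  cv_pair(halves$train, halves$test,
          k1 = position_bin + 1L + B, k2 = position_bin + 1L,
          neurons = neurons)
}

#' Signal and noise curves versus ensemble size, with asymptotic SNR
#'
#' Repeats the cross-validated signal/noise estimates over random neuron
#' subsets at each ensemble size, takes the median over adjacent-bin pairs
#' (both directions) within each subset, and averages over subsets. Straight
#' lines are fit to the per-size values restricted to sizes above
#' `slope_min_size` (100, the linear regime), and the asymptotic SNR is the
#' signal slope divided by the noise slope.
#'
#' @param tensor an [activity_tensor()].
#' @param sizes ensemble sizes.
#' @param n_subsets subsets per size (default 80).
#' @param seed integer seed.
#' @param shuffled if `TRUE`, trial-shuffle both halves (separately, per
#'   subset).
#' @param slope_min_size only sizes strictly above this enter the slope fits
#'   (default 100).
#' @return an `snr_record`: `curve` (data.frame size, signal, noise, snr),
#'   `signal_slope`, `noise_slope`, `asymptotic_snr`.
#' @export
snr_size_curves <- function(tensor, sizes, n_subsets = 80, seed = 1L,
                            shuffled = FALSE, slope_min_size = 100) {
  n_neurons <- dim(tensor$values)[1]
  if (max(sizes) > n_neurons) stop("size exceeds the neuron count")
  n_pairs <- (tensor$n_bins - 1L) * tensor$directions
  rows <- vector("list", length(sizes))
  for (si in seq_along(sizes)) {
    s <- sizes[si]
    sig <- noi <- numeric(n_subsets)
    for (j in seq_len(n_subsets)) {
      sub_seed <- seed + 1000L * si + j
      set.seed(sub_seed)
      neurons <- sample.int(n_neurons, s)
      work <- tensor
      halves <- split_trials(work, seed = sub_seed + 1L)
      if (shuffled) {
        halves$train <- trial_shuffle(halves$train, seed = sub_seed + 2L)
        halves$test <- trial_shuffle(halves$test, seed = sub_seed + 3L)
      }
      vals <- vapply(seq_len(n_pairs), function(p) {
        ks <- pair_classes(tensor, p)
        cv_pair(halves$train, halves$test, ks[1], ks[2], neurons)[1:2]
      }, numeric(2))
      sig[j] <- stats::median(vals[1, ])
      noi[j] <- stats::median(vals[2, ])
    }
    rows[[si]] <- data.frame(size = s, signal = mean(sig),
                             noise = mean(noi),
                             snr = mean(sig) / mean(noi))
  }
  curve <- do.call(rbind, rows)
  big <- curve$size > slope_min_size
  if (sum(big) < 2)
    stop("need at least 2 sizes above ", slope_min_size,
         " to fit the asymptotic slopes")
  sl_s <- unname(stats::coef(stats::lm(signal ~ size, curve[big, ]))[2])
  sl_n <- unname(stats::coef(stats::lm(noise ~ size, curve[big, ]))[2])
  structure(list(curve = curve, signal_slope = sl_s, noise_slope = sl_n,
                 asymptotic_snr = sl_s / sl_n),
            class = "snr_record")
}

#' @export
print.snr_record <- function(x, ...) {
  cat("signal/noise size curves:\n")
  print(x$curve, row.names = FALSE)
  cat(sprintf("slopes: signal %.4g, noise %.4g; asymptotic SNR %.4g\n",
              x$signal_slope, x$noise_slope, x$asymptotic_snr))
  invisible(x)
}

#' Single-cell signal-to-noise ratios
#'
#' Two per-cell definitions are computed and reported separately: (i) the
#' cross-validated pairwise form — the per-cell medians over adjacent-bin
#' pairs of the squared test-half mean difference and of the pooled
#' within-bin variance, ratioed; and (ii) the tuning-variance form —
#' variance between bins of the cell's trial-mean responses divided by the
#' mean within-bin trial variance.
#'
#' @param tensor an [activity_tensor()].
#' @param seed split seed for the pairwise form.
#' @return data.frame, one row per cell: `snr_pairs`, `snr_anova`,
#'   `zero_within` flag (within-bin variance was zero).
#' @export
single_cell_snr <- function(tensor, seed = 1L) {
  halves <- split_trials(tensor, seed)
  n <- dim(tensor$values)[1]
  K <- dim(tensor$values)[2]
  n_pairs <- (tensor$n_bins - 1L) * tensor$directions
  sig_med <- noi_med <- numeric(n)
  for (p in seq_len(n_pairs)) {
    ks <- pair_classes(tensor, p)
    s1 <- class_samples(halves$test, ks[1])
    s2 <- class_samples(halves$test, ks[2])
    dmu2 <- (colMeans(s2) - colMeans(s1))^2
    v <- ((nrow(s1) - 1) * apply(s1, 2, stats::var) +
            (nrow(s2) - 1) * apply(s2, 2, stats::var)) /
      (nrow(s1) + nrow(s2) - 2)
    if (p == 1L) { sig_all <- matrix(0, n, n_pairs); noi_all <- sig_all }
    sig_all[, p] <- dmu2; noi_all[, p] <- v
  }
  sig_med <- apply(sig_all, 1, stats::median)
  noi_med <- apply(noi_all, 1, stats::median)
  means <- vapply(seq_len(K), function(k) colMeans(class_samples(tensor, k)),
                  numeric(n))
  wivar <- vapply(seq_len(K),
                  function(k) apply(class_samples(tensor, k), 2, stats::var),
                  numeric(n))
  between <- apply(means, 1, stats::var)
  within <- rowMeans(wivar)
  data.frame(snr_pairs = ifelse(noi_med > 0, sig_med / noi_med, NA_real_),
             snr_anova = ifelse(within > 0, between / within, NA_real_),
             zero_within = within <= 0)
}

#' Pairwise noise correlations versus place-field peak distance
#'
#' Computes each neuron pair's Pearson correlation of residual activity
#' (activity minus the per-bin trial mean, pooled over bins within a
#' direction), groups pairs by the distance between the neurons' PF peaks
#' (bins), and reports the mean correlation per distance with bootstrap
#' confidence intervals over pairs. Information-limiting structure shows up
#' as correlations that decay with peak distance; after a trial shuffle the
#' profile is flat around zero.
#'
#' @param tensor an [activity_tensor()].
#' @param tuning optional [make_place_fields()] ground truth; if absent,
#'   peaks are estimated from the tensor's trial-mean tuning.
#' @param max_dist largest peak distance reported (default 10 bins).
#' @param n_boot bootstrap replicates (default 200).
#' @param seed bootstrap seed.
#' @return data.frame: `dist`, `mean_corr`, `ci_lo`, `ci_hi`, `n_pairs`.
#' @export
noise_correlation_profile <- function(tensor, tuning = NULL, max_dist = 10,
                                      n_boot = 200, seed = 1L) {
  d3 <- dim(tensor$values)
  if (d3[3] < 10) stop("need at least 10 trials")
  B <- tensor$n_bins
  n <- d3[1]
  set.seed(seed)
  acc <- vector("list", tensor$directions)
  for (d in seq_len(tensor$directions)) {
    if (is.null(tuning)) {
      tm <- vapply((d - 1L) * B + seq_len(B),
                   function(k) colMeans(class_samples(tensor, k)), numeric(n))
      peaks <- max.col(tm, ties.method = "first") - 1L
    } else {
      peaks <- tuning$peak_bins[, d]
    }
    res <- list()
    for (k in (d - 1L) * B + seq_len(B)) {
      m <- class_samples(tensor, k)
      res[[length(res) + 1L]] <- sweep(m, 2, colMeans(m))
    }
    R <- do.call(rbind, res)
    keep <- apply(R, 2, stats::sd) > 0
    if (sum(!keep) > 0)
      message(sum(!keep), " constant-residual neuron(s) excluded")
    C <- stats::cor(R[, keep, drop = FALSE])
    pk <- peaks[keep]
    ut <- upper.tri(C)
    acc[[d]] <- data.frame(corr = C[ut],
                           dist = abs(outer(pk, pk, "-"))[ut])
  }
  all_pairs <- do.call(rbind, acc)
  out <- lapply(0:max_dist, function(dd) {
    v <- all_pairs$corr[all_pairs$dist == dd]
    if (length(v) == 0)
      return(data.frame(dist = dd, mean_corr = NA, ci_lo = NA, ci_hi = NA,
                        n_pairs = 0L))
    bs <- replicate(n_boot, mean(sample(v, length(v), replace = TRUE)))
    data.frame(dist = dd, mean_corr = mean(v),
               ci_lo = unname(stats::quantile(bs, 0.025)),
               ci_hi = unname(stats::quantile(bs, 0.975)),
               n_pairs = length(v))
  })
  do.call(rbind, out)
}
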