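#' Train the one-vs-one linear-SVM position decoder
#'
#' Fits a multiclass ensemble of linear support vector machines over the
#' spatial-directional classes of an activity tensor: one binary classifier
#' per unordered class pair (C(40, 2) = 780 for a 20-bin, two-direction
#' track), each sample being the population activity vector of one bin visit.
#' The pairwise classifiers vote at prediction time; ties are broken by the
#' summed signed decision margins.
#'
#' @param tensor_train training [activity_tensor()].
#' @param seed integer seed.
#' @param cost SVM regularization parameter C (default 1, no class weights).
#' @param neurons optional neuron subset (indices).
#' @return a `decoder_model`: `svm` (the fitted libsvm ensemble), `classes`
#'   (0-based class ids present), `n_binary_classifiers`, `n_bins`,
#'   `bin_length`, `neurons`.
#' @export
train_decoder <- function(tensor_train, seed = 1L, cost = 1,
                          neurons = NULL) {
  stopifnot(inherits(tensor_train, "activity_tensor"))
  if (is.null(neurons)) neurons <- seq_len(dim(tensor_train$values)[1])
  K <- dim(tensor_train$values)[2]
  xs <- list(); ys <- integer(0)
  for (k in seq_len(K)) {
    m <- class_samples(tensor_train, k)[, neurons, drop = FALSE]
    if (nrow(m) < 2)
      stop("class ", k - 1L, " has fewer than 2 training samples")
    xs[[k]] <- m
    ys <- c(ys, rep(k - 1L, nrow(m)))
  }
  x <- do.call(rbind, xs)
  y <- factor(ys, levels = sort(unique(ys)))
  set.seed(seed)
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  structure(list(svm = fit,
                 classes = as.integer(levels(y)),
                 n_binary_classifiers = choose(nlevels(y), 2L),
                 n_bins = tensor_train$n_bins,
                 bin_length = tensor_train$bin_length,
                 neurons = neurons),
            class = "decoder_model")
}

# vote over the pairwise decision values; ties broken by summed signed margins
vote_classes <- function(model, x) {
  pr <- stats::predict(model$svm, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
  lvls <- as.character(model$classes)
  nl <- length(lvls)
  votes <- matrix(0L, nrow(dv), nl, dimnames = list(NULL, lvls))
  margin <- matrix(0, nrow(dv), nl, dimnames = list(NULL, lvls))
  for (j in seq_along(pairs)) {
    a <- pairs[[j]][1]; b <- pairs[[j]][2]
    pos <- dv[, j] >= 0
    votes[, a] <- votes[, a] + pos
    votes[, b] <- votes[, b] + !pos
    margin[, a] <- margin[, a] + dv[, j]
    margin[, b] <- margin[, b] - dv[, j]
  }
  out <- integer(nrow(dv))
  for (i in seq_len(nrow(dv))) {
    best <- which(votes[i, ] == max(votes[i, ]))
    if (length(best) > 1L)
      best <- best[which.max(margin[i, best])]
    out[i] <- model$classes[best]
  }
  out
}

#' Evaluate a decoder on held-out trials
#'
#' Predicts the spatial-directional class of every test sample and summarizes
#' accuracy as a confusion matrix, positional errors (distance in cm between
#' the centers of the predicted and true spatial bins — a direction error at
#' the correct position contributes 0 cm and is counted separately), per-bin
#' RMS error, and the overall mean squared error.
#'
#' @param model a [train_decoder()] result.
#' @param tensor_test test [activity_tensor()] (disjoint trials).
#' @return list: `confusion` (true x predicted, counts over all classes),
#'   `mse` (cm^2), `rms` (cm), `rms_per_bin` (cm per true class; `NA` where
#'   the test set has no samples), `direction_errors`, `n_samples`.
#' @export
evaluate_decoder <- function(model, tensor_test) {
  stopifnot(inherits(model, "decoder_model"),
            inherits(tensor_test, "activity_tensor"))
  K <- dim(tensor_test$values)[2]
  lvl <- 0:(K - 1L)
  conf <- matrix(0L, K, K, dimnames = list(true = lvl, predicted = lvl))
  sqerr <- numeric(0)
  per_bin <- stats::setNames(rep(NA_real_, K), lvl)
  dir_err <- 0L
  for (k in seq_len(K)) {
    m <- class_samples(tensor_test, k)[, model$neurons, drop = FALSE]
    if (nrow(m) == 0) next
    pred <- vote_classes(model, m)
    true_c <- class_center_cm(tensor_test, k)
    pred_c <- class_center_cm(tensor_test, pred + 1L)
    err <- abs(pred_c - true_c)
    conf[k, ] <- conf[k, ] + tabulate(pred + 1L, nbins = K)
    dir_err <- dir_err +
      sum(class_direction(tensor_test, pred + 1L) !=
            class_direction(tensor_test, k))
    sqerr <- c(sqerr, err^2)
    per_bin[k] <- sqrt(mean(err^2))
  }
  if (length(sqerr) == 0) stop("test tensor has no samples")
  list(confusion = conf,
       mse = mean(sqerr),
       rms = sqrt(mean(sqerr)),
       rms_per_bin = per_bin,
       direction_errors = dir_err,
       n_samples = length(sqerr))
}

#' IMSE as a function of ensemble size
#'
#' For each requested ensemble size, repeatedly samples a random neuron
#' subset (without replacement within a subset, independently across
#' subsets, so subsets are not necessarily disjoint), splits trials 50/50,
#' optionally trial-shuffles the training and testing halves separately,
#' trains the decoder and computes the inverse mean squared error 1/MSE of
#' the held-out predictions. Reports the mean over subsets per size.
#'
#' Subsets that happen to decode perfectly (MSE = 0, possible on clean
#' synthetic data) have no finite IMSE and are dropped with a warning.
#'
#' @param tensor an [activity_tensor()].
#' @param sizes ensemble sizes (each <= number of neurons, > 0).
#' @param n_subsets random subsets per size (default 80).
#' @param seed integer seed.
#' @param shuffled if `TRUE`, apply the trial shuffle (separately per subset
#'   and per train/test half).
#' @param cost SVM regularization.
#' @return an `imse_curve` data.frame: `size`, `imse` (1/cm^2), `sem`,
#'   `n_used`.
#' @export
imse_curve <- function(tensor, sizes, n_subsets = 80, seed = 1L,
                       shuffled = FALSE, cost = 1) {
  stopifnot(inherits(tensor, "activity_tensor"),
            all(sizes >= 1), n_subsets >= 1)
  n_neurons <- dim(tensor$values)[1]
  if (max(sizes) > n_neurons) stop("size exceeds the neuron count")
  rows <- vector("list", length(sizes))
  dropped <- 0L
  for (si in seq_along(sizes)) {
    s <- sizes[si]
    vals <- numeric(n_subsets)
    for (j in seq_len(n_subsets)) {
      sub_seed <- seed + 1000L * si + j
      set.seed(sub_seed)
      neurons <- sample.int(n_neurons, s)
      halves <- split_trials(tensor, seed = sub_seed + 1L)
      if (shuffled) {
        halves$train <- trial_shuffle(halves$train, seed = sub_seed + 2L)
        halves$test <- trial_shuffle(halves$test, seed = sub_seed + 3L)
      }
      model <- train_decoder(halves$train, seed = sub_seed, cost = cost,
                             neurons = neurons)
      mse <- evaluate_decoder(model, halves$test)$mse
      vals[j] <- if (mse > 0) 1 / mse else NA_real_
    }
    dropped <- dropped + sum(is.na(vals))
    vals <- vals[!is.na(vals)]
    rows[[si]] <- data.frame(size = s,
                             imse = mean(vals),
                             sem = stats::sd(vals) / sqrt(length(vals)),
                             n_used = length(vals))
  }
  if (dropped > 0)
    warning(dropped, " subset(s) decoded perfectly (MSE = 0) and were dropped")
  out <- do.call(rbind, rows)
  class(out) <- c("imse_curve", class(out))
  out
}

#' Fit the IMSE saturation curve
#'
#' Fits \eqn{IMSE(n) = I_0 n / (1 + n/N)}: \eqn{I_0} is the initial slope
#' (per-neuron information at small ensembles), N the ensemble size where
#' the IMSE reaches half its asymptote \eqn{I_0 N}. The fit is initialized
#' by the linear regression of 1/IMSE on 1/n (the model is linear in that
#' parameterization) and refined by nonlinear least squares. Derived
#' saturation points: the size where the slope of the fitted curve falls to
#' 5% of \eqn{I_0}, \eqn{(\sqrt{20} - 1) N \approx 3.47 N}, and the size
#' reaching 95% of the asymptote, \eqn{19 N}.
#'
#' @param curve an [imse_curve()] result, or a data.frame with `size` and
#'   `imse` columns.
#' @param weights optional per-point weights for the refinement.
#' @return a `saturation_fit`: `I0`, `N`, `asymptote`, `n_slope5`,
#'   `n_asymp95`, `fitted` (function of n), `converged`.
#' @examples
#' n <- c(25, 50, 100, 200, 400)
#' fit <- fit_saturation(data.frame(size = n, imse = 1 * n / (1 + n / 100)))
#' c(fit$I0, fit$N)  # 1 and 100
#' @export
fit_saturation <- function(curve, weights = NULL) {
  sizes <- curve$size
  imse <- curve$imse
  ok <- is.finite(imse) & imse > 0
  sizes <- sizes[ok]; imse <- imse[ok]
  if (length(unique(sizes)) < 3)
    stop("need at least 3 distinct sizes with finite IMSE")
  # 1/IMSE = (1/I0)(1/n) + 1/(I0 N): convex initialization
  lin <- stats::lm(I(1 / imse) ~ I(1 / sizes))
  slope <- unname(stats::coef(lin)[2]); icpt <- unname(stats::coef(lin)[1])
  I0_0 <- if (slope > 0) 1 / slope else imse[1] / sizes[1]
  N_0 <- if (icpt > 0 && slope > 0) slope / icpt else max(sizes) * 10
  N_0 <- min(max(N_0, 1e-3), 1e8)
  dat <- data.frame(n = sizes, y = imse)
  if (is.null(weights)) weights <- rep(1, nrow(dat))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ I0 * n / (1 + n / N), data = dat,
                      start = list(I0 = I0_0, N = N_0),
                      lower = c(1e-12, 1e-6), upper = c(Inf, 1e9),
                      weights = weights,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("saturation fit failed to converge: ", conditionMessage(fit))
  cf <- stats::coef(fit)
  I0 <- unname(cf["I0"]); N <- unname(cf["N"])
  structure(list(I0 = I0, N = N,
                 asymptote = I0 * N,
                 n_slope5 = (sqrt(20) - 1) * N,
                 n_asymp95 = 19 * N,
                 fitted = function(n) I0 * n / (1 + n / N),
                 converged = TRUE),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("IMSE saturation fit: I0 = %.4g, N = %.4g (asymptote %.4g)\n",
              x$I0, x$N, x$asymptote))
  cat(sprintf("  5%%-slope point: %.4g neurons; 95%%-asymptote point: %.4g\n",
              x$n_slope5, x$n_asymp95))
  invisible(x)
}

#' Aggregate saturation points across sessions and animals
#'
#' Sessions from the same animal are combined with a geometric mean (to
#' mitigate outliers); the range across animals is reported.
#'
#' @param values per-session values (e.g. `n_slope5`).
#' @param animal per-session animal labels.
#' @return list: `per_animal` (named geometric means), `range`.
#' @export
aggregate_saturation <- function(values, animal) {
  stopifnot(length(values) == length(animal), all(values > 0))
  gm <- tapply(values, animal, function(v) exp(mean(log(v))))
  list(per_animal = gm, range = range(gm))
}
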