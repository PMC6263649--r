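## Frame-level walk detection.  Three single-statistic detectors (variance
## threshold, STFT band energy in [0.66, 1.66] Hz, smoothed db10 level-7/8
## detail energy) share one exhaustively fitted threshold rule; two
## machine-learning detectors (k-NN with k = 5, SVM with RBF kernel) use
## the full frame feature vector.  All are scored by stratified 10-fold
## cross-validation on a 1:1 balanced dataset.

WD_ALGOS <- c("thr", "stft", "dwt", "knn", "svm")
WD_BAND <- c(0.66, 1.66)

#' Per-frame variance statistic
#' @param x signal (magnitude or one axis).
#' @param frames a `frame_set`.
#' @return numeric vector, one value per frame.
#' @export
frame_variance <- function(x, frames) {
  vapply(seq_len(nrow(frames)),
         function(i) stats::var(frame_samples(x, frames, i)), 0)
}

#' Per-frame spectral energy in the walk band
#'
#' One-sided FFT energy summed over the closed band [0.66, 1.66] Hz, the
#' canonical stride-frequency band; amplitudes are scaled by 2/N so the
#' statistic is comparable across sampling rates at fixed window duration.
#'
#' @param x signal.
#' @param frames a `frame_set`.
#' @param rate_hz sampling rate (must satisfy rate > 2 * band max).
#' @param band closed frequency band in Hz.
#' @return numeric vector, one value per frame.
#' @export
frame_band_energy <- function(x, frames, rate_hz, band = WD_BAND) {
  if (rate_hz <= 2 * band[2]) stop("band extends to or above Nyquist")
  vapply(seq_len(nrow(frames)), function(i) {
    s <- frame_samples(x, frames, i)
    n <- length(s)
    sp <- (Mod(stats::fft(s)) * 2 / n)^2
    f <- (seq_len(n) - 1) * rate_hz / n
    sel <- f >= band[1] & f <= band[2]
    sum(sp[sel])
  }, 0)
}

#' Per-frame smoothed wavelet detail energy
#'
#' Squared db10 detail coefficients of levels 7 and 8 (the 0.39-1.56 Hz
#' band at 200 Hz; levels shift by round(log2(200/rate)) at other rates)
#' are mapped back to sample positions, smoothed by a 1 s moving average,
#' and averaged within each frame.
#'
#' @param x whole signal (the decomposition is global, not per frame).
#' @param frames a `frame_set`.
#' @param rate_hz sampling rate.
#' @param levels base detail levels at the 200 Hz reference rate.
#' @return numeric vector, one value per frame.
#' @export
frame_dwt_energy <- function(x, frames, rate_hz, levels = c(7L, 8L)) {
  shift <- as.integer(round(log2(200 / rate_hz)))
  lev <- levels - shift
  lev <- lev[lev >= 1L]
  if (!length(lev)) stop("detail levels unavailable at this rate")
  dec <- dwt_decompose(x - mean(x), levels = max(lev))
  lev <- lev[lev <= dec$levels]
  if (!length(lev)) stop("signal too short for the requested decomposition depth")
  e <- dwt_detail_energy(dec, lev)
  w <- max(1L, round(rate_hz))          # 1 s moving average
  sm <- as.numeric(stats::filter(e, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- 0
  vapply(seq_len(nrow(frames)),
         function(i) mean(frame_samples(sm, frames, i)), 0)
}

#' Fit a scalar decision threshold by exhaustive scan
#'
#' Scans all candidate thresholds between the minimum and maximum of the
#' training statistic (midpoints between consecutive sorted distinct
#' values, plus the two extremes) and returns the one maximizing training
#' accuracy of the rule "walk iff statistic >= threshold"; ties go to the
#' smallest threshold.
#'
#' @param stat numeric statistic per training frame.
#' @param y factor/logical walk labels.
#' @param statistic name stored on the model.
#' @return object of class `wd_model` (threshold, statistic, train_accuracy).
#' @export
thr_fit <- function(stat, y, statistic = "variance") {
  walk <- if (is.logical(y)) y else y == "walk"
  if (all(walk) || !any(walk)) stop("both classes must be present to fit a threshold")
  u <- sort(unique(stat))
  cand <- unique(c(u[1], if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, u[length(u)]))
  acc <- vapply(cand, function(th) mean((stat >= th) == walk), 0)
  best <- cand[acc == max(acc)]
  structure(list(threshold = min(best), statistic = statistic,
                 train_accuracy = max(acc)),
            class = "wd_model")
}

#' @export
print.wd_model <- function(x, ...) {
  cat(sprintf("<wd_model> walk iff %s >= %.6g (training accuracy %.3f)\n",
              x$statistic, x$threshold, x$train_accuracy))
  invisible(x)
}

#' Predict walk frames from a fitted threshold model
#' @param object a `wd_model`.
#' @param stat statistic per frame.
#' @param ... unused.
#' @return logical vector (TRUE = walk).
#' @export
predict.wd_model <- function(object, stat, ...) {
  stat >= object$threshold
}

## stratified fold assignment, seeded
stratified_folds <- function(y, folds, seed) {
  set.seed(as.integer(seed))
  f <- integer(length(y))
  for (cl in levels(factor(y))) {
    i <- which(y == cl)
    if (length(i) < folds) stop("fewer samples than folds in class ", cl)
    f[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  f
}

ml_fit_predict_fold <- function(xtr, ytr, xte, algo) {
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  xtr <- scale(xtr, mu, sdv); xte <- scale(xte, mu, sdv)
  if (algo == "knn") {
    as.character(class::knn(xtr, xte, cl = ytr, k = 5))
  } else {
    d <- ncol(xtr)
    grid <- expand.grid(cost = c(1, 10), gamma = c(1, 4) / d)
    cv_acc <- vapply(seq_len(nrow(grid)), function(i) {
      fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = grid$cost[i],
                        gamma = grid$gamma[i], cross = 2)
      fit$tot.accuracy
    }, 0)
    b <- which.max(cv_acc)
    fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = grid$cost[b],
                      gamma = grid$gamma[b])
    as.character(stats::predict(fit, xte))
  }
}

#' Cross-validated walk detection
#'
#' Stratified k-fold cross-validation of one detector on a balanced
#' dataset.  Single-statistic detectors (thr, stft, dwt) refit their
#' threshold on each training split by [thr_fit()]; k-NN (k = 5) and the
#' RBF SVM (cost/gamma chosen by a small inner grid) standardize features
#' per training fold.  Accuracy is the pooled fraction of correct frames.
#'
#' @param x statistic vector (thr/stft/dwt) or feature matrix (knn/svm).
#' @param y factor with levels walk/nonwalk.
#' @param algo one of "thr", "stft", "dwt", "knn", "svm".
#' @param folds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @return list(prediction, accuracy, algo, folds).
#' @export
wd_evaluate <- function(x, y, algo = WD_ALGOS, folds = 10L, seed = 1L) {
  algo <- match.arg(algo)
  y <- factor(y, levels = c("walk", "nonwalk"))
  fold <- stratified_folds(y, folds, seed)
  pred <- character(length(y))
  for (k in seq_len(folds)) {
    te <- fold == k
    if (algo %in% c("thr", "stft", "dwt")) {
      m <- thr_fit(x[!te], y[!te], statistic = algo)
      pred[te] <- ifelse(predict(m, x[te]), "walk", "nonwalk")
    } else {
      pred[te] <- ml_fit_predict_fold(x[!te, , drop = FALSE], y[!te],
                                      x[te, , drop = FALSE], algo)
    }
  }
  list(prediction = factor(pred, levels = levels(y)),
       accuracy = mean(pred == as.character(y)),
       algo = algo, folds = folds)
}

#' Rotate a recording by a fixed proper rotation
#'
#' Applies one rotation matrix to all samples (the magnitude is invariant).
#'
#' @param recording an `accel_recording`.
#' @param rot 3x3 proper rotation matrix.
#' @return rotated `accel_recording`.
#' @export
rotate_recording <- function(recording, rot) {
  stopifnot(inherits(recording, "accel_recording"),
            max(abs(crossprod(rot) - diag(3))) < 1e-8)
  s <- cbind(recording$ax, recording$ay, recording$az) %*% t(rot)
  new_recording(recording$time_s, s[, 1], s[, 2], s[, 3], recording$rate_hz,
                units = recording$units, placement = recording$placement,
                subject = recording$subject, labels = recording$labels)
}
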