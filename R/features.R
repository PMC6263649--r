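#' Frame feature vector for the machine-learning walk detectors
#'
#' Computes the standard time/frequency frame features: mean, variance,
#' min, max, energy (mean of squares, so rms^2 = energy), skewness and
#' excess kurtosis (population moments; 0 by convention on zero-variance
#' frames), mean-crossing rate (sign changes of x - mean(x) per second,
#' plateaus counted once), rms, and the first K one-sided FFT amplitude
#' bins after the DC bin (Hann-windowed, scaled 2|X|/N so amplitudes are
#' rate-independent at fixed window duration).
#'
#' @param x frame samples (length >= 8).
#' @param rate_hz sampling rate.
#' @param K number of FFT amplitude bins (default 32).
#' @return named numeric vector of length 9 + K.
#' @export
extract_features <- function(x, rate_hz, K = 32L) {
  n <- length(x)
  if (n < 8) stop("frame too short for feature extraction (need >= 8 samples)")
  mu <- mean(x)
  v <- mean((x - mu)^2)
  if (v > 1e-24) {
    skew <- mean((x - mu)^3) / v^1.5
    kurt <- mean((x - mu)^4) / v^2 - 3
    ctr <- x - mu
    sgn <- sign(ctr)
    sgn_nz <- sgn[sgn != 0]
    mcr <- if (length(sgn_nz) > 1) sum(diff(sgn_nz) != 0) / (n / rate_hz) else 0
  } else {
    skew <- 0; kurt <- 0; mcr <- 0
  }
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))   # Hann
  sp <- abs(stats::fft(x * win)) * 2 / n
  K <- as.integer(K)
  famp <- sp[seq(2L, length.out = K)]              # skip DC
  famp[is.na(famp)] <- 0
  out <- c(mean = mu, variance = v, min = min(x), max = max(x),
           energy = mean(x^2), skewness = skew, kurtosis = kurt,
           mcr = mcr, rms = sqrt(mean(x^2)), stats::setNames(famp, paste0("fft", seq_len(K))))
  out
}

## features for every frame; axes = "magnitude" or "xyz" (orientation known)
frame_features <- function(recording, frames, axes = c("magnitude", "xyz"),
                           K = 32L) {
  axes <- match.arg(axes)
  rate <- recording$rate_hz
  if (axes == "magnitude") {
    m <- magnitude(recording)
    mat <- t(vapply(seq_len(nrow(frames)),
                    function(i) extract_features(frame_samples(m, frames, i), rate, K),
                    numeric(9 + K)))
  } else {
    per_axis <- lapply(list(x = recording$ax, y = recording$ay, z = recording$az),
                       function(ch) t(vapply(seq_len(nrow(frames)),
                                             function(i) extract_features(frame_samples(ch, frames, i), rate, K),
                                             numeric(9 + K))))
    for (a in names(per_axis)) colnames(per_axis[[a]]) <- paste(a, colnames(per_axis[[a]]), sep = "_")
    mat <- do.call(cbind, per_axis)
  }
  mat
}

#' Build a balanced walk / non-walk dataset
#'
#' Maps frame activity labels to the binary walk label, balances the two
#' classes 1:1 by seeded random subsampling of the majority class, and
#' shuffles the rows.  Returns the selected row indices so per-frame
#' metadata (subject, placement) can be carried along.
#'
#' @param features feature matrix, one row per frame.
#' @param labels activity (or logical walk) label per frame.
#' @param seed RNG seed for subsampling and shuffling.
#' @return list(x = matrix, y = factor("walk","nonwalk"), idx = row indices).
#' @export
build_dataset <- function(features, labels, seed = 1L) {
  if (is.logical(labels)) walk <- labels else walk <- labels == "walk"
  keep <- !is.na(walk)
  idx_all <- which(keep)
  walk <- walk[keep]
  n_w <- sum(walk); n_n <- sum(!walk)
  if (n_w == 0 || n_n == 0) stop("both classes must be present to build a dataset")
  set.seed(as.integer(seed))
  n_min <- min(n_w, n_n)
  iw <- idx_all[walk]; inw <- idx_all[!walk]
  if (n_w > n_min) iw <- sort(sample(iw, n_min))
  if (n_n > n_min) inw <- sort(sample(inw, n_min))
  idx <- c(iw, inw)
  ord <- sample(length(idx))
  idx <- idx[ord]
  y <- factor(ifelse(idx %in% iw, "walk", "nonwalk"), levels = c("walk", "nonwalk"))
  list(x = features[idx, , drop = FALSE], y = y, idx = idx)
}
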