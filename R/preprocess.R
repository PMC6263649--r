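#' Magnitude of a tri-axial recording
#'
#' Per-sample Euclidean norm sqrt(x^2 + y^2 + z^2).  The magnitude is
#' invariant to sensor orientation, which is why all orientation-agnostic
#' detectors and counters operate on it.  A static sensor reads a constant
#' 1 g (gravity is kept in).
#'
#' @param recording an `accel_recording`.
#' @return numeric vector with attribute `rate_hz`.
#' @export
magnitude <- function(recording) {
  stopifnot(inherits(recording, "accel_recording"))
  m <- sqrt(recording$ax^2 + recording$ay^2 + recording$az^2)
  attr(m, "rate_hz") <- recording$rate_hz
  m
}

#' Zero-phase Butterworth low-pass filter
#'
#' 4th-order Butterworth applied forward-backward (unit DC gain, zero phase
#' so peak timing is preserved for step counting).  A cutoff at or above the
#' Nyquist frequency is clipped to 0.45 * rate with a warning: at low
#' sampling rates the nominal cutoffs (15 Hz for walk detection, 50 Hz in
#' the Pan-Tompkins chain) can exceed what the rate supports.
#'
#' @param x numeric signal.
#' @param cutoff_hz cutoff frequency (> 0).
#' @param rate_hz sampling rate.
#' @return filtered signal, same length.
#' @export
lowpass <- function(x, cutoff_hz, rate_hz) {
  stopifnot(is.numeric(x), cutoff_hz > 0, rate_hz > 0)
  nyq <- rate_hz / 2
  if (cutoff_hz >= nyq) {
    cutoff_hz <- 0.45 * rate_hz
    warning(sprintf("cutoff clipped to %.3g Hz (0.45 * rate); requested value is above Nyquist",
                    cutoff_hz))
  }
  bf <- signal::butter(4, cutoff_hz / nyq, type = "low")
  ## odd-reflection padding and mean removal tame the forward-backward
  ## filter's edge transients (the filter starts from zero state)
  n <- length(x)
  mu <- mean(x)
  xc <- x - mu
  pad <- min(n - 1L, max(27L, ceiling(3 * rate_hz / cutoff_hz)))
  pre <- 2 * xc[1] - xc[(pad + 1):2]
  post <- 2 * xc[n] - xc[(n - 1):(n - pad)]
  y <- as.numeric(signal::filtfilt(bf, c(pre, xc, post)))
  y[(pad + 1):(pad + n)] + mu
}

#' Segment a signal into overlapping frames
#'
#' Frames of `window_s` seconds advance by `window_s - overlap_s`; a
#' trailing partial frame is discarded.  When `overlap_s` is NULL the
#' one-sixth rule applies: overlap = window / 6 (so the canonical 3 s
#' window gets the canonical 0.5 s overlap).  If activity labels are given,
#' each frame is tagged with the majority activity of its samples; ties are
#' broken toward the non-walk activity (conservative for walk detection).
#'
#' @param x numeric signal.
#' @param rate_hz sampling rate.
#' @param window_s frame length in seconds (must not exceed the signal).
#' @param overlap_s overlap in seconds, or NULL for window/6.
#' @param labels optional data.frame(start_s, end_s, activity).
#' @return data.frame of class `frame_set` with 0-based half-open
#'   `start_idx`/`end_idx` and `label`; attributes window_s, overlap_s,
#'   hop_s, rate_hz.
#' @export
frame_signal <- function(x, rate_hz, window_s = 3, overlap_s = NULL,
                         labels = NULL) {
  n <- length(x)
  if (is.null(overlap_s)) overlap_s <- window_s / 6
  stopifnot(window_s > 0, overlap_s >= 0, overlap_s < window_s)
  w <- round(window_s * rate_hz)
  hop <- round((window_s - overlap_s) * rate_hz)
  if (w > n) stop("window longer than signal")
  starts <- seq(0L, n - w, by = hop)
  frames <- data.frame(start_idx = starts, end_idx = starts + w)
  frames$label <- NA_character_
  if (!is.null(labels)) {
    sample_act <- rep(NA_character_, n)
    for (i in seq_len(nrow(labels))) {
      i0 <- floor(labels$start_s[i] * rate_hz) + 1L
      i1 <- min(n, ceiling(labels$end_s[i] * rate_hz))
      sample_act[i0:i1] <- labels$activity[i]
    }
    frames$label <- vapply(seq_len(nrow(frames)), function(i) {
      acts <- sample_act[(frames$start_idx[i] + 1L):frames$end_idx[i]]
      tab <- sort(table(acts), decreasing = TRUE)
      if (length(tab) == 0) return(NA_character_)
      top <- names(tab)[tab == tab[1]]
      if (length(top) > 1 && "walk" %in% top) top <- setdiff(top, "walk")
      top[1]
    }, "")
  }
  structure(frames, class = c("frame_set", "data.frame"),
            window_s = window_s, overlap_s = overlap_s,
            hop_s = window_s - overlap_s, rate_hz = rate_hz)
}

## extract the samples of frame i (frames use 0-based half-open indices)
frame_samples <- function(x, frames, i) {
  x[(frames$start_idx[i] + 1L):frames$end_idx[i]]
}

#' Variance normalization
#'
#' Removes the mean and scales to unit variance, making amplitudes
#' comparable across subjects, placements and intensities before step
#' counting (peak/valley thresholds then sit symmetrically around 0).
#'
#' @param x numeric signal with positive variance.
#' @return normalized signal.
#' @export
normalize_variance <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12)
    stop("degenerate input: (near-)constant signal cannot be variance-normalized")
  (x - mean(x)) / s
}

#' Resample a recording to a lower rate
#'
#' Fourier resampling of all three axes (and the time base) to
#' `target_rate_hz`: the spectrum is truncated at the new Nyquist
#' frequency (an ideal anti-alias filter) and inverted on the new grid, so
#' in-band sinusoids keep their amplitude.  Only downsampling (or the
#' identity) is allowed: the study design samples at the reference 200 Hz
#' and evaluates lower rates by decimation.
#'
#' @param recording an `accel_recording`.
#' @param target_rate_hz target rate, <= the recording's rate.
#' @return resampled `accel_recording` (labels carried over; durations are
#'   preserved within one sample).
#' @export
resample_recording <- function(recording, target_rate_hz) {
  stopifnot(inherits(recording, "accel_recording"))
  r0 <- recording$rate_hz
  if (target_rate_hz > r0) stop("upsampling above the source rate is not supported")
  if (target_rate_hz == r0) return(recording)
  n <- length(recording$ax)
  n_out <- round(n * target_rate_hz / r0)
  res <- function(x) fft_resample(x, n_out)
  ax <- res(recording$ax); ay <- res(recording$ay); az <- res(recording$az)
  n <- length(ax)
  new_recording((seq_len(n_out) - 1) / target_rate_hz, ax, ay, az,
                target_rate_hz, units = recording$units,
                placement = recording$placement, subject = recording$subject,
                labels = recording$labels)
}

## truncate the spectrum at the new Nyquist and invert on the new grid
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  half <- floor(n_out / 2)
  Y <- complex(length.out = n_out)
  Y[1] <- X[1]
  if (half >= 2) {
    Y[2:half] <- X[2:half]
    Y[n_out - (2:half) + 2] <- X[n - (2:half) + 2]
  }
  if (n_out %% 2 == 0) Y[half + 1] <- Re(X[half + 1])   # shared Nyquist bin
  Re(stats::fft(Y, inverse = TRUE)) / n
}
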