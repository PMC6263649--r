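## Step-event detection.  Every counter transforms the (normalized)
## magnitude into a score signal whose local maxima mark candidate step
## events, then prunes candidates with detect_peaks().  The per-event score
## (peak height in the transformed signal) is the single variable swept to
## trace a per-cycle ROC.

new_step_detections <- function(index, score, rate_hz, algo, params = list()) {
  ord <- order(index)
  structure(data.frame(index = as.integer(index[ord]),
                       time_s = index[ord] / rate_hz,
                       score = score[ord]),
            class = c("step_detections", "data.frame"),
            rate_hz = rate_hz, algo = algo, params = params)
}

#' @export
print.step_detections <- function(x, ...) {
  cat(sprintf("<step_detections> %d events, algorithm %s\n",
              nrow(x), attr(x, "algo")))
  invisible(x)
}

local_maxima <- function(x) {
  ## plateau-aware: collapse equal runs; a run is a maximum when the value
  ## before it is lower and the value after it is lower; event index is the
  ## first sample of the run (ties to the earlier sample).  Signal ends do
  ## not qualify.
  r <- rle(x)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-k]))
  is_max <- c(FALSE, r$values[2:(k - 1)] > r$values[1:(k - 2)] &
                     r$values[2:(k - 1)] > r$values[3:k], FALSE)
  starts[is_max]
}

peak_prominence <- function(x, peaks) {
  ## classic prominence: on each side, the minimum between the peak and the
  ## nearest strictly higher sample (or the signal end); prominence is the
  ## height above the larger of the two side minima.
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1)]
    hi <- which(left > h)
    lmin <- min(left[seq(from = if (length(hi)) max(hi) else 1L, to = p - 1L)])
    right <- x[seq(p + 1, length(x))]
    hi <- which(right > h)
    rmin <- min(right[seq_len(if (length(hi)) min(hi) else length(right))])
    h - max(lmin, rmin)
  }, 0)
}

#' Detect and prune step-event peaks
#'
#' Finds local maxima of a transformed signal, keeps those passing the
#' minimum height, minimum prominence and decision threshold, then greedily
#' prunes by minimum distance: candidates are visited in decreasing height
#' (ties to the earlier index) and a candidate is kept only if no kept peak
#' lies within `min_distance_s`.  The decision threshold on the peak score
#' is the variable swept to trace an ROC; raising it can never increase the
#' event count.
#'
#' @param x transformed (score) signal, finite.
#' @param rate_hz sampling rate.
#' @param min_height minimum absolute peak height.
#' @param min_distance_s minimum separation between kept events (s).
#' @param min_prominence minimum peak prominence; NULL uses 0.1 * IQR(x).
#' @param threshold decision threshold on the peak score.
#' @param algo label stored on the result.
#' @return a `step_detections` object (0-based indices, scores = heights).
#' @export
detect_peaks <- function(x, rate_hz, min_height = -Inf, min_distance_s = 0.25,
                         min_prominence = NULL, threshold = -Inf,
                         algo = "peaks") {
  stopifnot(all(is.finite(x)), min_distance_s > 0)
  if (is.null(min_prominence)) min_prominence <- 0.1 * stats::IQR(x)
  cand <- local_maxima(x)
  if (length(cand)) {
    h <- x[cand]
    prom <- peak_prominence(x, cand)
    ok <- h >= min_height & h >= threshold & prom >= min_prominence
    cand <- cand[ok]; h <- h[ok]
  }
  if (length(cand)) {
    ord <- order(-h, cand)
    min_gap <- min_distance_s * rate_hz
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept) || all(abs(cand[kept] - cand[i]) >= min_gap)) kept <- c(kept, i)
    }
    cand <- cand[sort(kept)]
  }
  new_step_detections(cand - 1L, x[cand], rate_hz, algo,
                      list(min_height = min_height,
                           min_distance_s = min_distance_s,
                           min_prominence = min_prominence,
                           threshold = threshold))
}

#' Finite-state-machine step counter configuration
#'
#' Four thresholds on the variance-normalized magnitude with the ordering
#' t1 > t2 >= 0 >= t3 > t4.
#'
#' @param t1,t2,t3,t4 state thresholds.
#' @return list of class `fsm_config`.
#' @export
fsm_config <- function(t1, t2, t3, t4) {
  if (!(t1 > t2 && t2 >= 0 && 0 >= t3 && t3 > t4))
    stop("invalid FSM thresholds: need t1 > t2 >= 0 >= t3 > t4")
  structure(list(t1 = t1, t2 = t2, t3 = t3, t4 = t4), class = "fsm_config")
}

#' Finite-state-machine step counter
#'
#' Five-state traversal of the normalized magnitude: IDLE -> RISING
#' (x > t2) -> PEAK (x > t1) -> FALLING (x < t3) -> VALLEY (x < t4).  On
#' valley confirmation one step event is emitted at the maximum of the
#' PEAK phase (its height is the event score) and the machine returns to
#' IDLE; incomplete traversals emit nothing.
#'
#' @param xn variance-normalized magnitude.
#' @param config an [fsm_config()].
#' @param rate_hz sampling rate.
#' @return a `step_detections` object.
#' @export
fsm_count <- function(xn, config, rate_hz) {
  stopifnot(inherits(config, "fsm_config"))
  state <- "IDLE"
  peak_val <- -Inf; peak_idx <- NA_integer_
  idx <- integer(0); sc <- numeric(0)
  for (i in seq_along(xn)) {
    v <- xn[i]
    if (state == "IDLE") {
      if (v > config$t2) state <- "RISING"
    } else if (state == "RISING") {
      if (v > config$t1) { state <- "PEAK"; peak_val <- v; peak_idx <- i }
      else if (v < config$t3) state <- "IDLE"
    } else if (state == "PEAK") {
      if (v > peak_val) { peak_val <- v; peak_idx <- i }
      if (v < config$t3) state <- "FALLING"
    } else if (state == "FALLING") {
      if (v < config$t4) {
        idx <- c(idx, peak_idx); sc <- c(sc, peak_val)
        state <- "IDLE"; peak_val <- -Inf; peak_idx <- NA_integer_
      } else if (v > config$t1) {
        state <- "PEAK"
        if (v > peak_val) { peak_val <- v; peak_idx <- i }
      }
    }
  }
  new_step_detections(idx - 1L, sc, rate_hz, "fsm", unclass(config))
}

default_fsm_grid <- function() {
  expand.grid(t1 = c(0.5, 0.8, 1.2, 1.6, 2.0),
              t2 = c(0, 0.1, 0.3),
              t3 = c(-0.1, -0.3, -0.5),
              t4 = c(-0.6, -0.9, -1.3))
}

#' Grid search for the FSM thresholds
#'
#' Evaluates every valid threshold combination of the grid on an annotated
#' training bout and returns the configuration maximizing the strict
#' per-cycle TPR subject to FPR <= `fpr_budget`; ties go to the larger t1
#' (the stricter peak threshold).  If no configuration meets the budget the
#' one with the smallest FPR (then largest TPR) is returned with a warning.
#'
#' @param xn variance-normalized magnitude of the training bout.
#' @param truth a `gait_truth` for the bout.
#' @param rate_hz sampling rate.
#' @param grid data.frame of candidate (t1, t2, t3, t4); default
#'   a coarse 5x3x3x3 lattice.
#' @param fpr_budget strict FPR budget (default 0.05).
#' @return the selected `fsm_config`.
#' @export
fsm_grid_search <- function(xn, truth, rate_hz, grid = default_fsm_grid(),
                            fpr_budget = 0.05) {
  valid <- grid$t1 > grid$t2 & grid$t2 >= 0 & grid$t3 <= 0 & grid$t3 > grid$t4
  grid <- grid[valid, , drop = FALSE]
  if (nrow(grid) == 0) stop("empty feasible grid")
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- fsm_config(grid$t1[i], grid$t2[i], grid$t3[i], grid$t4[i])
    det <- fsm_count(xn, cfg, rate_hz)
    m <- strict_match(det, truth)
    list(cfg = cfg, tpr = m$tpr, fpr = m$fpr)
  })
  tpr <- vapply(res, `[[`, 0, "tpr")
  fpr <- vapply(res, `[[`, 0, "fpr")
  feas <- fpr <= fpr_budget
  if (any(feas)) {
    cand <- which(feas)
    cand <- cand[tpr[cand] == max(tpr[cand])]
    cand <- cand[which.max(grid$t1[cand])]
  } else {
    warning("no FSM configuration met the FPR budget; returning the lowest-FPR one")
    cand <- which(fpr == min(fpr))
    cand <- cand[which.max(tpr[cand])]
  }
  res[[cand]]$cfg
}

#' Pan-Tompkins step counter
#'
#' The classic event-detection chain adapted to gait: linear-phase FIR
#' low-pass (order 200, 50 Hz cutoff, clipped below Nyquist at low rates),
#' first-difference differentiator, pointwise squaring, and a 0.5 s
#' moving-window integrator.  One local maximum of the integrator output
#' marks one step; maxima are pruned by [detect_peaks()].
#'
#' @param mag magnitude signal (need not be normalized; squaring makes the
#'   event indices amplitude-invariant).
#' @param rate_hz sampling rate.
#' @param filter_order FIR order (default 200).
#' @param cutoff_hz low-pass cutoff (default 50 Hz).
#' @param integrator_s integrator window (default 0.5 s).
#' @param ... passed to [detect_peaks()].
#' @return a `step_detections` object (scores = integrator peak heights).
#' @export
ptm_count <- function(mag, rate_hz, filter_order = 200, cutoff_hz = 50,
                      integrator_s = 0.5, ...) {
  n <- length(mag)
  if (n <= filter_order + round(integrator_s * rate_hz))
    stop("bout shorter than the filter transient")
  nyq <- rate_hz / 2
  if (cutoff_hz >= nyq) {
    cutoff_hz <- 0.45 * rate_hz
    message(sprintf("ptm: cutoff clipped to %.3g Hz (below Nyquist)", cutoff_hz))
  }
  h <- signal::fir1(filter_order, cutoff_hz / nyq, type = "low")
  lp <- as.numeric(stats::filter(mag, h, sides = 2))    # symmetric FIR: zero phase
  lp[is.na(lp)] <- lp[which(!is.na(lp))[1]]
  half <- floor(filter_order / 2)
  lp[(n - half + 1):n] <- lp[n - half]
  d <- c(diff(lp), 0) * rate_hz
  sq <- d^2
  wi <- round(integrator_s * rate_hz)
  integ <- as.numeric(stats::filter(sq, rep(1 / wi, wi), sides = 2))
  integ[is.na(integ)] <- 0
  detect_peaks(integ, rate_hz, algo = "ptm", ...)
}

#' Spectral-sparsification step counter
#'
#' Keeps the largest-magnitude FFT coefficients (conjugate-symmetric pairs
#' together) until their cumulative energy reaches `energy_frac` (20%) of
#' the total spectral energy, inverse-transforms, differentiates, and
#' detects peaks.  With `mode = "lowfreq"` coefficients are instead kept
#' from the low-frequency end until the energy budget is met (the
#' alternative reading of the energy filter).
#'
#' @param xn variance-normalized magnitude (zero mean, so the retained
#'   coefficients describe the gait oscillation rather than gravity).
#' @param rate_hz sampling rate.
#' @param energy_frac cumulative energy fraction to retain (default 0.2).
#' @param mode "magnitude" (default) or "lowfreq".
#' @param ... passed to [detect_peaks()].
#' @return a `step_detections` object.
#' @export
stft_count <- function(xn, rate_hz, energy_frac = 0.2,
                       mode = c("magnitude", "lowfreq"), ...) {
  mode <- match.arg(mode)
  n <- length(xn)
  if (n < 4 * rate_hz) stop("bout too short for spectral step counting (need >= 4 s)")
  X <- stats::fft(xn)
  e <- Mod(X)^2
  tot <- sum(e)
  if (tot < 1e-20) stop("degenerate all-zero spectrum")
  ## pair bin k (1-based, k >= 2) with its conjugate n - k + 2; DC and (for
  ## even n) the Nyquist bin are self-paired
  pair_of <- function(k) ifelse(k == 1L, 1L, n - k + 2L)
  half <- seq_len(floor(n / 2) + 1L)
  pe <- e[half] + ifelse(pair_of(half) != half, e[pair_of(half)], 0)
  ord <- if (mode == "magnitude") half[order(-pe, half)] else half
  csum <- cumsum(pe[match(ord, half)])
  kstop <- which(csum >= energy_frac * tot)[1]
  if (is.na(kstop)) kstop <- length(ord)
  keep <- ord[seq_len(kstop)]
  mask <- logical(n)
  mask[keep] <- TRUE
  mask[pair_of(keep)] <- TRUE
  Xs <- X; Xs[!mask] <- 0
  rec <- Re(stats::fft(Xs, inverse = TRUE)) / n
  d <- c(diff(rec), 0) * rate_hz
  detect_peaks(d, rate_hz, algo = "stft", ...)
}

#' Wavelet-reconstruction step counter
#'
#' 8-level db10 decomposition of the magnitude; the signal is reconstructed
#' from the detail levels of the chosen variant only ("dwt": levels
#' {6,7,8}, the gait band at 200 Hz; "dwt2": levels {2,3}, the fine-detail
#' band) and peaks of the reconstruction are detected.  Stated levels
#' assume the 200 Hz reference rate; at other rates they are shifted by
#' round(log2(200 / rate)) so the passband stays put.
#'
#' @param mag magnitude signal.
#' @param rate_hz sampling rate.
#' @param variant "dwt" or "dwt2".
#' @param ... passed to [detect_peaks()].
#' @return a `step_detections` object.
#' @export
dwt_count <- function(mag, rate_hz, variant = c("dwt", "dwt2"), ...) {
  variant <- match.arg(variant)
  base_levels <- if (variant == "dwt") c(6L, 7L, 8L) else c(2L, 3L)
  shift <- as.integer(round(log2(200 / rate_hz)))
  levels <- base_levels - shift
  levels <- levels[levels >= 1L]
  if (!length(levels)) stop("requested detail levels unavailable at this rate")
  depth <- max(levels)
  dec <- dwt_decompose(mag - mean(mag), levels = max(8L - shift, depth))
  if (dec$levels < depth) stop("signal too short for the requested decomposition depth")
  rec <- dwt_reconstruct(dec, keep_levels = levels, keep_approx = FALSE)
  detect_peaks(rec, rate_hz, algo = variant, ...)
}

#' Halve a Group II event stream
#'
#' Group II placements show two signal periods per gait cycle, so a counter
#' tuned to one event per period reports two events per cycle; keeping every
#' other event restores one step per cycle before strict matching.
#'
#' @param det a `step_detections` object.
#' @return a `step_detections` with the odd-numbered events kept.
#' @export
halve_events <- function(det) {
  stopifnot(inherits(det, "step_detections"))
  keep <- seq(1L, nrow(det), by = 2L)
  new_step_detections(det$index[keep], det$score[keep], attr(det, "rate_hz"),
                      attr(det, "algo"),
                      c(attr(det, "params"), list(halved = TRUE)))
}

#' Count steps in a walking bout
#'
#' Front door to the step counters: variance-normalizes the magnitude,
#' dispatches to the requested counter, and for Group II placements halves
#' the event stream (two observed periods per gait cycle).
#'
#' @param recording an `accel_recording` of a walking bout.
#' @param algo one of "ptm", "stft", "fsm", "dwt", "dwt2".
#' @param fsm a fitted [fsm_config()] (required for algo = "fsm").
#' @param hand_group Group override for the Hand placement.
#' @param ... passed to the underlying counter.
#' @return a `step_detections` object; `nrow()` is the estimated count Cest.
#' @export
count_steps <- function(recording, algo = c("ptm", "stft", "fsm", "dwt", "dwt2"),
                        fsm = NULL, hand_group = "I", ...) {
  algo <- match.arg(algo)
  mag <- magnitude(recording)
  rate <- recording$rate_hz
  xn <- normalize_variance(mag)
  det <- switch(algo,
    ptm = ptm_count(mag, rate, ...),
    stft = stft_count(xn, rate, ...),
    dwt = dwt_count(mag, rate, variant = "dwt", ...),
    dwt2 = dwt_count(mag, rate, variant = "dwt2", ...),
    fsm = {
      if (is.null(fsm)) stop("algo = 'fsm' needs a fitted fsm_config")
      fsm_count(xn, fsm, rate)
    })
  placement <- recording$placement
  if (!is.na(placement) && placement_group(placement, hand_group) == "II")
    det <- halve_events(det)
  det
}
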