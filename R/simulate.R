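## Synthetic tri-axial accelerometer gait generator.
##
## A walking bout is modelled in the body frame as a constant 1 g gravity
## axis plus a periodic dynamic component: a small set of harmonics of the
## observed fundamental plus one sharp negative heel-strike impulse per
## observed period.  Placements fall into two groups: Group I placements
## (sensor on the instrumented leg or swinging with it) show one signal
## period per gait cycle, Group II placements (trunk-carried) pick up both
## legs and show two periods per gait cycle.  The body-frame signal is
## rotated by an arbitrary proper rotation (free sensor orientation) and
## white Gaussian noise is added per axis.

PLACEMENTS <- c("Foot", "FrontPocket", "BackPocket", "UpPocket", "Hand", "HandU")
ACTIVITIES <- c("walk", "stairs_up", "stairs_down", "run", "ride",
                "brush_teeth", "drive", "bus", "sit", "stand", "other")

#' Placement group (one vs. two observed periods per gait cycle)
#'
#' Group I placements (Foot, FrontPocket, BackPocket and, by default, Hand)
#' show one signal period per gait cycle of the instrumented leg; Group II
#' placements (UpPocket) show two, because the contralateral leg contributes
#' a period as well.  Hand sits on the boundary between the groups; it is
#' assigned to Group I unless `hand_group = "II"`.
#'
#' @param placement one of Foot, FrontPocket, BackPocket, UpPocket, Hand, HandU.
#' @param hand_group group override for the Hand placement ("I" or "II").
#' @return "I" or "II".
#' @export
placement_group <- function(placement, hand_group = "I") {
  placement <- match.arg(placement, PLACEMENTS)
  hand_group <- match.arg(hand_group, c("I", "II"))
  switch(placement,
         Foot = , FrontPocket = , BackPocket = , HandU = "I",
         UpPocket = "II",
         Hand = hand_group)
}

#' Uniformly random proper rotation matrix
#'
#' QR-based sampling from the Haar measure on SO(3); used to emulate free
#' sensor orientation.
#'
#' @param rng_state unused; rotation is drawn from the current RNG stream.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @export
random_rotation <- function(rng_state = NULL) {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  d <- diag(qr.R(qr_d))
  q <- q %*% diag(sign(d))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Gait model parameters
#'
#' @param stride_frequency_hz gait-cycle fundamental in Hz; NULL draws one
#'   uniformly from [0.8, 1.2] (inside the canonical walk band
#'   [0.66, 1.66] Hz).
#' @param harmonics amplitudes (g) of the harmonics of the observed
#'   fundamental, at least 3.
#' @param impulse_amplitude heel-strike impulse depth (g, applied negative).
#' @param impulse_width_s heel-strike impulse Gaussian width (s).
#' @param noise_sd white noise s.d. per axis (g).
#' @param placement wearing placement (see [placement_group()]).
#' @param periods_per_cycle 1 (Group I) or 2 (Group II); NULL derives it
#'   from the placement.
#' @param subject_scale multiplicative amplitude factor for the subject.
#' @param orientation 3x3 proper rotation, NULL to draw a random one, or
#'   "identity" for a known orientation (gravity on z).
#' @param hand_jitter extra low-frequency wander amplitude (g) modelling
#'   diverse hand movement; only meaningful for Hand/HandU.
#' @param hand_group group override for Hand (see [placement_group()]).
#' @return list of class `gait_params`.
#' @export
gait_params <- function(stride_frequency_hz = NULL,
                        harmonics = c(0.35, 0.15, 0.08),
                        impulse_amplitude = 0.4,
                        impulse_width_s = 0.03,
                        noise_sd = 0.02,
                        placement = "FrontPocket",
                        periods_per_cycle = NULL,
                        subject_scale = 1,
                        orientation = NULL,
                        hand_jitter = 0,
                        hand_group = "I") {
  placement <- match.arg(placement, PLACEMENTS)
  if (is.null(periods_per_cycle)) {
    periods_per_cycle <- if (placement_group(placement, hand_group) == "II") 2L else 1L
  }
  stopifnot(periods_per_cycle %in% c(1L, 2L), length(harmonics) >= 3,
            impulse_amplitude >= 0, noise_sd >= 0, subject_scale > 0)
  if (is.matrix(orientation)) {
    stopifnot(nrow(orientation) == 3, ncol(orientation) == 3,
              max(abs(crossprod(orientation) - diag(3))) < 1e-8,
              det(orientation) > 0)
  }
  structure(list(stride_frequency_hz = stride_frequency_hz,
                 harmonics = harmonics,
                 impulse_amplitude = impulse_amplitude,
                 impulse_width_s = impulse_width_s,
                 noise_sd = noise_sd,
                 placement = placement,
                 periods_per_cycle = as.integer(periods_per_cycle),
                 subject_scale = subject_scale,
                 orientation = orientation,
                 hand_jitter = hand_jitter),
            class = "gait_params")
}

new_recording <- function(time_s, ax, ay, az, rate_hz, units = "g",
                          placement = NA_character_, subject = NA_integer_,
                          labels = NULL) {
  structure(list(time_s = time_s, ax = ax, ay = ay, az = az,
                 rate_hz = rate_hz, units = units, placement = placement,
                 subject = subject, labels = labels),
            class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> %d samples @ %g Hz (%.1f s), units %s\n",
              length(x$ax), x$rate_hz, length(x$ax) / x$rate_hz, x$units))
  if (!is.na(x$placement)) cat("  placement:", x$placement, "\n")
  if (!is.null(x$labels))
    cat("  labels:", nrow(x$labels), "segments (",
        paste(unique(x$labels$activity), collapse = ", "), ")\n")
  invisible(x)
}

#' @export
print.gait_truth <- function(x, ...) {
  cat(sprintf("<gait_truth> %d gait cycles (Cgt = %d)\n", nrow(x$cycles), x$n_cycles))
  invisible(x)
}

gauss_pulse_train <- function(t, centers, amplitude, width_s) {
  y <- numeric(length(t))
  if (amplitude == 0 || length(centers) == 0) return(y)
  half <- 4 * width_s
  for (tc in centers) {
    i0 <- max(1L, floor((tc - half) * length(t) / (t[length(t)] + t[2])))
    sel <- which(abs(t - tc) <= half)
    y[sel] <- y[sel] - amplitude * exp(-(t[sel] - tc)^2 / (2 * width_s^2))
  }
  y
}

#' Simulate a steady-cadence walking bout
#'
#' Generates a tri-axial recording plus per-gait-cycle ground truth.  The
#' body-frame vertical channel carries the harmonic burst and one negative
#' heel-strike impulse per observed period; the horizontal channels carry
#' attenuated copies in quadrature.  The signal is rotated by the (possibly
#' random) orientation and degraded by white noise.  One annotated gait
#' cycle corresponds to one counted step of the instrumented side.
#'
#' @param params a [gait_params()] object.
#' @param duration_s bout length in seconds; must contain at least 3 cycles.
#' @param rate_hz sampling rate in [5, 200] Hz.
#' @param seed integer seed; all randomness (fundamental, phases,
#'   orientation, noise) derives from it.
#' @return list with `recording` (class accel_recording) and `truth`
#'   (class gait_truth: 0-based half-open cycle index ranges and Cgt).
#' @export
simulate_walk <- function(params = gait_params(), duration_s, rate_hz = 200,
                          seed = 1L) {
  stopifnot(inherits(params, "gait_params"),
            rate_hz >= 5, rate_hz <= 200, duration_s > 0)
  set.seed(as.integer(seed))
  f <- params$stride_frequency_hz
  if (is.null(f)) f <- stats::runif(1, 0.8, 1.2)
  if (f * params$periods_per_cycle >= rate_hz / 2)
    stop("stride frequency at or above Nyquist for this rate")
  n_cycles <- as.integer(floor(duration_s * f))
  if (n_cycles < 3) stop("duration too short: fewer than 3 gait cycles")

  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  f_obs <- f * params$periods_per_cycle
  sc <- params$subject_scale

  ## harmonics are phase-locked to the gait event (one global random phase
  ## per bout): a cosine series peaking once per observed period, the shape
  ## of an impact-driven oscillation
  t0 <- stats::runif(1, 0, 1 / f_obs)
  vert <- numeric(n)
  for (h in seq_along(params$harmonics)) {
    vert <- vert + sc * params$harmonics[h] * cos(2 * pi * h * f_obs * (t - t0))
  }
  ## heel-strike impulse at the waveform valley, half a period off the peak
  period_starts <- seq(t0 - 1 / f_obs, by = 1 / f_obs,
                       length.out = floor(duration_s * f_obs) + 2L)
  vert <- vert + gauss_pulse_train(t, period_starts + 0.5 / f_obs,
                                   sc * params$impulse_amplitude,
                                   params$impulse_width_s)
  fwd <- 0.3 * sc * params$harmonics[1] * cos(2 * pi * f_obs * (t - t0) + pi / 2)
  lat <- 0.2 * sc * params$harmonics[1] * cos(2 * pi * f_obs * (t - t0) + pi / 4)
  if (params$hand_jitter > 0) {
    drift_f <- stats::runif(3, 0.1, 0.4)
    drift_p <- stats::runif(3, 0, 2 * pi)
    fwd <- fwd + params$hand_jitter * sin(2 * pi * drift_f[1] * t + drift_p[1])
    lat <- lat + params$hand_jitter * sin(2 * pi * drift_f[2] * t + drift_p[2])
    vert <- vert + params$hand_jitter * sin(2 * pi * drift_f[3] * t + drift_p[3])
  }

  body <- cbind(fwd, lat, vert + 1)       # gravity on body z
  rot <- params$orientation
  if (is.null(rot)) rot <- random_rotation()
  if (identical(rot, "identity")) rot <- diag(3)
  sens <- body %*% t(rot)
  if (params$noise_sd > 0) sens <- sens + matrix(stats::rnorm(3 * n, 0, params$noise_sd), n, 3)

  rec <- new_recording(t, sens[, 1], sens[, 2], sens[, 3], rate_hz,
                       placement = params$placement,
                       labels = data.frame(start_s = 0, end_s = duration_s,
                                           activity = "walk"))
  ## cycle annotations are phase-aligned with the gait events (as a human
  ## annotator would mark them): boundaries sit between the heel impulse of
  ## one cycle and the harmonic peak of the previous one, so every event
  ## lies in a cycle interior
  start_t <- t0 - 0.75 / f + (seq_len(n_cycles) - 1) / f
  end_t <- start_t + 1 / f
  start_t[1] <- max(0, start_t[1])
  end_t[n_cycles] <- min(duration_s, end_t[n_cycles])
  cycles <- data.frame(cycle_start_idx = pmax(floor(start_t * rate_hz), 0),
                       cycle_end_idx = pmin(floor(end_t * rate_hz), n))
  truth <- structure(list(cycles = cycles, n_cycles = n_cycles,
                          stride_frequency_hz = f,
                          periods_per_cycle = params$periods_per_cycle),
                     class = "gait_truth")
  list(recording = rec, truth = truth)
}

activity_model_table <- function() {
  ## fundamental (Hz), harmonic amplitudes (g), impulse (g), base noise (g)
  list(
    stairs_up   = list(fund = 0.70, harm = c(0.30, 0.12, 0.05), impulse = 0.25),
    stairs_down = list(fund = 0.75, harm = c(0.32, 0.14, 0.05), impulse = 0.30),
    run         = list(fund = 2.60, harm = c(0.60, 0.25, 0.10), impulse = 0.60),
    ride        = list(fund = 4.00, harm = c(0.05, 0.02, 0.01), impulse = 0),
    brush_teeth = list(fund = 1.30, harm = c(0.25, 0.10, 0.03), impulse = 0),
    drive       = list(fund = 0.30, harm = c(0.05, 0.01, 0.005), impulse = 0),
    bus         = list(fund = 0.40, harm = c(0.08, 0.02, 0.01), impulse = 0),
    sit         = list(fund = NA, harm = c(0, 0, 0), impulse = 0),
    stand       = list(fund = NA, harm = c(0, 0, 0), impulse = 0),
    other       = list(fund = NA, harm = c(0, 0, 0), impulse = 0, burst = 0.2)
  )
}

#' Simulate a non-walk activity
#'
#' Periodic activities (stairs, running, riding, tooth-brushing, vehicle
#' sway) are generated from the same harmonic model as walking with
#' activity-specific fundamentals and amplitudes; static activities (sit,
#' stand) produce gravity plus noise only; "other" produces irregular
#' noise bursts.  Running's fundamental (2.6 Hz) lies above the walk band,
#' tooth-brushing's (1.3 Hz) inside it.
#'
#' @param activity activity name (closed vocabulary, excluding "walk").
#' @param duration_s,rate_hz,seed as in [simulate_walk()].
#' @param noise_sd white noise s.d. (g).
#' @param amplitude_scale multiplicative amplitude factor.
#' @param orientation as in [gait_params()].
#' @param placement wearing placement tag.
#' @param fundamental_hz,harmonics,impulse optional overrides of the
#'   activity model (e.g. to give stair bouts a subject-specific cadence
#'   and intensity); NULL keeps the table defaults.
#' @return an `accel_recording` with a single label segment.
#' @export
simulate_activity <- function(activity, duration_s, rate_hz = 200, seed = 1L,
                              noise_sd = 0.02, amplitude_scale = 1,
                              orientation = NULL, placement = "FrontPocket",
                              fundamental_hz = NULL, harmonics = NULL,
                              impulse = NULL) {
  tab <- activity_model_table()
  if (identical(activity, "walk"))
    stop("use simulate_walk() for walking (it carries gait annotations)")
  if (!activity %in% names(tab)) stop("unknown activity: ", activity)
  m <- tab[[activity]]
  if (!is.null(fundamental_hz)) m$fund <- fundamental_hz
  if (!is.null(harmonics)) m$harm <- harmonics
  if (!is.null(impulse)) m$impulse <- impulse
  set.seed(as.integer(seed))
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  vert <- numeric(n)
  if (!is.na(m$fund)) {
    ## same phase-locked shape as walking: movement harmonics ride on the
    ## periodic event (step on a stair, brush stroke, pedal turn)
    t0 <- stats::runif(1, 0, 1 / m$fund)
    for (h in seq_along(m$harm)) {
      vert <- vert + amplitude_scale * m$harm[h] * cos(2 * pi * h * m$fund * (t - t0))
    }
    if (m$impulse > 0) {
      centers <- seq(t0 - 1 / m$fund, by = 1 / m$fund,
                     length.out = floor(duration_s * m$fund) + 2L)
      vert <- vert + gauss_pulse_train(t, centers + 0.5 / m$fund,
                                       amplitude_scale * m$impulse, 0.03)
    }
  }
  if (!is.null(m$burst)) {
    ## sparse irregular bursts
    nb <- max(1L, round(duration_s / 5))
    ctr <- stats::runif(nb, 0, duration_s)
    for (tc in ctr) {
      sel <- abs(t - tc) < 0.5
      vert[sel] <- vert[sel] + m$burst * amplitude_scale * stats::rnorm(sum(sel)) *
        exp(-(t[sel] - tc)^2 / (2 * 0.15^2))
    }
  }
  fwd <- if (!is.na(m$fund)) 0.3 * vert else numeric(n)
  lat <- if (!is.na(m$fund)) 0.2 * vert else numeric(n)
  body <- cbind(fwd, lat, vert + 1)
  rot <- orientation
  if (is.null(rot)) rot <- random_rotation()
  if (identical(rot, "identity")) rot <- diag(3)
  sens <- body %*% t(rot)
  if (noise_sd > 0) sens <- sens + matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3)
  new_recording(t, sens[, 1], sens[, 2], sens[, 3], rate_hz,
                placement = placement,
                labels = data.frame(start_s = 0, end_s = duration_s,
                                    activity = activity))
}

#' Compose a labelled multi-activity session
#'
#' Concatenates simulated activity bouts into one recording with exact label
#' segments; walking bouts carry gait-cycle annotations (offset into the
#' session).  Each bout draws its own sub-seed from `seed` so permuting the
#' plan permutes segments without changing their content.
#'
#' @param plan data.frame with columns `activity` and `duration_s` (or a
#'   list of `(activity, duration)` pairs).
#' @param rate_hz sampling rate.
#' @param seed session seed.
#' @param params a [gait_params()] template used for walking bouts.
#' @param noise_sd,amplitude_scale passed to [simulate_activity()].
#' @param orientation one rotation for the whole session (NULL = random,
#'   drawn from `seed`).
#' @param activity_overrides named list (by activity) of override lists
#'   (`fundamental_hz`, `harmonics`, `impulse`) forwarded to
#'   [simulate_activity()].
#' @return list with `recording` (labels attached) and `truth` (gait_truth
#'   pooled over the walking bouts).
#' @export
compose_session <- function(plan, rate_hz = 200, seed = 1L,
                            params = gait_params(), noise_sd = NULL,
                            amplitude_scale = 1, orientation = NULL,
                            activity_overrides = list()) {
  if (is.list(plan) && !is.data.frame(plan)) {
    plan <- data.frame(activity = vapply(plan, function(p) as.character(p[[1]]), ""),
                       duration_s = vapply(plan, function(p) as.numeric(p[[2]]), 0))
  }
  stopifnot(is.data.frame(plan), nrow(plan) >= 1,
            all(plan$activity %in% ACTIVITIES))
  if (is.null(noise_sd)) noise_sd <- params$noise_sd
  set.seed(as.integer(seed))
  if (is.null(orientation)) orientation <- random_rotation()
  sub_seeds <- sample.int(.Machine$integer.max, nrow(plan))

  ax <- ay <- az <- numeric(0)
  labels <- NULL
  cycles <- NULL
  n_cycles <- 0L
  offset_idx <- 0L
  offset_s <- 0
  for (i in seq_len(nrow(plan))) {
    act <- plan$activity[i]
    dur <- plan$duration_s[i]
    if (act == "walk") {
      p <- params
      p$orientation <- orientation
      p$noise_sd <- noise_sd
      p$subject_scale <- params$subject_scale * amplitude_scale
      sim <- simulate_walk(p, dur, rate_hz, sub_seeds[i])
      rec <- sim$recording
      cyc <- sim$truth$cycles
      cyc$cycle_start_idx <- cyc$cycle_start_idx + offset_idx
      cyc$cycle_end_idx <- cyc$cycle_end_idx + offset_idx
      cycles <- rbind(cycles, cyc)
      n_cycles <- n_cycles + sim$truth$n_cycles
    } else {
      ov <- activity_overrides[[act]]
      rec <- simulate_activity(act, dur, rate_hz, sub_seeds[i],
                               noise_sd = noise_sd,
                               amplitude_scale = amplitude_scale,
                               orientation = orientation,
                               placement = params$placement,
                               fundamental_hz = ov$fundamental_hz,
                               harmonics = ov$harmonics,
                               impulse = ov$impulse)
    }
    ax <- c(ax, rec$ax); ay <- c(ay, rec$ay); az <- c(az, rec$az)
    labels <- rbind(labels, data.frame(start_s = offset_s,
                                       end_s = offset_s + dur,
                                       activity = act))
    offset_idx <- offset_idx + length(rec$ax)
    offset_s <- offset_s + dur
  }
  n <- length(ax)
  rec <- new_recording((seq_len(n) - 1) / rate_hz, ax, ay, az, rate_hz,
                       placement = params$placement, labels = labels)
  truth <- structure(list(cycles = cycles, n_cycles = n_cycles,
                          stride_frequency_hz = params$stride_frequency_hz,
                          periods_per_cycle = params$periods_per_cycle),
                     class = "gait_truth")
  list(recording = rec, truth = truth)
}

#' Per-subject gait variation profile
#'
#' Personalization is emulated by a multiplicative amplitude factor and a
#' stride-frequency offset drawn once per subject id (deterministically from
#' the base seed), so two sessions of the same subject share a regime.
#'
#' @param subject integer subject id.
#' @param base_seed study seed.
#' @param amp_range range of the amplitude factor (log-uniform).
#' @param freq_range range of the subject stride frequency (Hz).
#' @return list(amp_scale, stride_frequency_hz).
#' @export
subject_profile <- function(subject, base_seed = 1L,
                            amp_range = c(0.6, 1.8),
                            freq_range = c(0.8, 1.2)) {
  set.seed(as.integer(base_seed) * 1000L + as.integer(subject))
  list(amp_scale = exp(stats::runif(1, log(amp_range[1]), log(amp_range[2]))),
       stride_frequency_hz = stats::runif(1, freq_range[1], freq_range[2]))
}
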