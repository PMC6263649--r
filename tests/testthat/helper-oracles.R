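# Independent brute-force oracles used to validate the fast implementations.

# Per-cycle strict matcher: literal loop over cycles, counting events inside
# each half-open [start, end) range; n > 0 events in a cycle give 1 TP and
# n - 1 FP, events inside no cycle are FP.
oracle_strict_match <- function(event_idx, cycles) {
  ctp <- 0L; cfp <- 0L
  claimed <- rep(FALSE, length(event_idx))
  for (i in seq_len(nrow(cycles))) {
    inside <- event_idx >= cycles$cycle_start_idx[i] &
      event_idx < cycles$cycle_end_idx[i]
    n <- sum(inside)
    claimed[inside] <- TRUE
    if (n > 0) { ctp <- ctp + 1L; cfp <- cfp + n - 1L }
  }
  cfp <- cfp + sum(!claimed)
  list(Ctp = ctp, Cfp = cfp, Cgt = nrow(cycles),
       tpr = ctp / nrow(cycles), fpr = cfp / nrow(cycles))
}

# Exhaustive O(n^2) peak detector: enumerate plateau-aware local maxima,
# compute prominence by scanning outwards, filter, then repeatedly keep the
# highest remaining candidate (ties to the earlier index) and discard all
# others within the minimum distance.
oracle_detect_peaks <- function(x, rate_hz, min_height = -Inf,
                                min_distance_s = 0.25, min_prominence = 0,
                                threshold = -Inf) {
  n <- length(x)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L
    if (x[i] > x[i - 1L] && j < n && x[j + 1L] < x[i]) cand <- c(cand, i)
    i <- j + 1L
  }
  keep_mask <- vapply(cand, function(p) {
    h <- x[p]
    lmin <- Inf
    for (q in seq(p - 1L, 1L)) { if (x[q] > h) break; lmin <- min(lmin, x[q]) }
    rmin <- Inf
    for (q in seq(p + 1L, n)) { if (x[q] > h) break; rmin <- min(rmin, x[q]) }
    prom <- h - max(min(lmin, h), min(rmin, h))
    h >= min_height && h >= threshold && prom >= min_prominence
  }, TRUE)
  cand <- cand[keep_mask]
  kept <- integer(0)
  remaining <- cand
  min_gap <- min_distance_s * rate_hz
  while (length(remaining)) {
    best <- remaining[order(-x[remaining], remaining)][1]
    kept <- c(kept, best)
    remaining <- remaining[abs(remaining - best) >= min_gap]
  }
  sort(kept) - 1L   # 0-based, as the implementation reports
}

# Brute-force best threshold for the rule "walk iff stat >= t": scan the
# same candidate set definition (extremes plus midpoints of consecutive
# distinct values) by direct accuracy evaluation.
oracle_best_split <- function(stat, walk) {
  u <- sort(unique(stat))
  cand <- u[1]
  if (length(u) > 1) cand <- c(u[1], (u[-length(u)] + u[-1]) / 2, u[length(u)])
  cand <- unique(cand)
  acc <- sapply(cand, function(th) mean((stat >= th) == walk))
  list(threshold = min(cand[acc == max(acc)]), accuracy = max(acc))
}

# Direct sliding-window enumeration for frame counting.
oracle_frame_count <- function(n, w, hop) {
  count <- 0L; s <- 0L
  while (s + w <= n) { count <- count + 1L; s <- s + hop }
  count
}

# A small clean walking bout reused across tests.
clean_walk <- function(duration_s = 60, rate_hz = 200, seed = 2,
                       noise_sd = 0, f = 1.0, placement = "FrontPocket") {
  simulate_walk(gait_params(stride_frequency_hz = f, noise_sd = noise_sd,
                            orientation = "identity", placement = placement),
                duration_s, rate_hz, seed)
}
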