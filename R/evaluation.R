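#' Walk-detection error and accuracy
#'
#' Frame-level disagreement between a binary prediction and the state
#' ground truth: error = sum over frames of |s_t - f_t|; accuracy is its
#' complement as a fraction of the frame count.
#'
#' @param prediction logical/0-1 vector (TRUE = walk).
#' @param truth logical/0-1 vector, same length.
#' @return list(error, accuracy).
#' @export
wd_error <- function(prediction, truth) {
  stopifnot(length(prediction) == length(truth))
  p <- as.integer(as.logical(prediction))
  s <- as.integer(as.logical(truth))
  err <- sum(abs(s - p))
  list(error = err, accuracy = 1 - err / length(s))
}

#' Step-counting error
#'
#' Relative count error |n - Cest| / n and the signed loose variant
#' (Cest - n) / n * 100 (in percent); the relative error can exceed 1 when
#' the counter over-reports by more than the true count.
#'
#' @param cest estimated step count.
#' @param n_true true step count (> 0).
#' @return list(relative, loose_pct).
#' @export
sc_error <- function(cest, n_true) {
  stopifnot(n_true > 0)
  list(relative = abs(n_true - cest) / n_true,
       loose_pct = (cest - n_true) / n_true * 100)
}

#' Strict per-gait-cycle matching of step detections
#'
#' For each annotated gait cycle containing n > 0 detected events, one true
#' positive and n - 1 false positives are scored; cycles with no event are
#' misses; events falling outside every cycle count as false positives
#' (spurious detections are what the strict definition penalizes).
#' TPR = Ctp / Cgt and FPR = Cfp / Cgt; the FPR can exceed 1.
#'
#' @param detections a `step_detections` object (or 0-based event indices).
#' @param truth a `gait_truth` (or data.frame of 0-based half-open
#'   cycle_start_idx / cycle_end_idx rows).
#' @return object of class `strict_sc_metrics`: Ctp, Cfp, Cgt, Cest,
#'   misses, tpr, fpr, loose_pct.
#' @export
strict_match <- function(detections, truth) {
  idx <- if (inherits(detections, "step_detections")) detections$index else as.integer(detections)
  cyc <- if (inherits(truth, "gait_truth")) truth$cycles else truth
  cgt <- nrow(cyc)
  if (cgt == 0) stop("no annotated gait cycles (Cgt = 0)")
  ## cycles are ordered and non-overlapping: locate each event by its start
  pos <- findInterval(idx, cyc$cycle_start_idx)
  inside <- pos >= 1 & idx < cyc$cycle_end_idx[pmax(pos, 1L)]
  counts <- tabulate(pos[inside], nbins = cgt)
  ctp <- sum(counts > 0)
  cfp <- sum(pmax(counts - 1L, 0L)) + sum(!inside)
  cest <- length(idx)
  structure(list(Ctp = ctp, Cfp = cfp, Cgt = cgt, Cest = cest,
                 misses = cgt - ctp, tpr = ctp / cgt, fpr = cfp / cgt,
                 loose_pct = (cest - cgt) / cgt * 100),
            class = "strict_sc_metrics")
}

#' @export
print.strict_sc_metrics <- function(x, ...) {
  cat(sprintf("<strict_sc_metrics> Cgt %d  Ctp %d  Cfp %d  (Cest %d)\n",
              x$Cgt, x$Ctp, x$Cfp, x$Cest))
  cat(sprintf("  TPR %.4f  FPR %.4f  loose %+.2f%%\n", x$tpr, x$fpr, x$loose_pct))
  invisible(x)
}

#' Strict per-cycle ROC curve
#'
#' Sweeps the decision threshold over the detection scores: at each
#' threshold only events with score >= threshold survive (equivalent to
#' re-running the pruned detection at that threshold, since greedy
#' prune-by-height commutes with score thresholding) and strict matching is
#' recomputed.  Points are ordered by decreasing threshold, so TPR and FPR
#' are non-decreasing along the curve.
#'
#' @param detections an unthresholded `step_detections` object.
#' @param truth a `gait_truth`.
#' @param thresholds decreasing threshold grid; NULL uses +Inf followed by
#'   the sorted unique scores.
#' @return data.frame of class `sc_roc`: threshold, fpr, tpr.
#' @export
roc_curve <- function(detections, truth, thresholds = NULL) {
  stopifnot(inherits(detections, "step_detections"))
  if (is.null(thresholds))
    thresholds <- c(Inf, sort(unique(detections$score), decreasing = TRUE))
  thresholds <- sort(thresholds, decreasing = TRUE)
  pts <- lapply(thresholds, function(th) {
    m <- strict_match(detections$index[detections$score >= th], truth)
    data.frame(threshold = th, fpr = m$fpr, tpr = m$tpr)
  })
  structure(do.call(rbind, pts), class = c("sc_roc", "data.frame"),
            algo = attr(detections, "algo"))
}

#' @export
plot.sc_roc <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "b", xlab = "strict FPR", ylab = "strict TPR",
       main = paste("per-cycle ROC:", attr(x, "algo")), ...)
  invisible(x)
}

#' Operating point nearest a target FPR
#'
#' Selects the ROC point whose FPR is closest to the target; ties go to
#' the lower FPR (the stricter operating point), then to the higher TPR.
#'
#' @param roc an `sc_roc`.
#' @param fpr_target target false-positive rate (e.g. 0.03 or 0.05).
#' @return one-row data.frame (threshold, fpr, tpr).
#' @export
roc_operating_point <- function(roc, fpr_target = 0.05) {
  d <- abs(roc$fpr - fpr_target)
  cand <- which(d == min(d))
  cand <- cand[roc$fpr[cand] == min(roc$fpr[cand])]
  cand <- cand[which.max(roc$tpr[cand])]
  roc[cand, , drop = FALSE]
}

#' Error-source distribution across placements
#'
#' At a common operating point (ROC point with FPR nearest the target,
#' ties to the lower FPR) computes each placement's share of the total
#' false positives; shares sum to 1.
#'
#' @param runs named list (by placement) of lists with elements
#'   `detections` and `truth`.
#' @param fpr_target common operating-point FPR (default 0.05).
#' @return data.frame(placement, cfp, share).
#' @export
error_sources <- function(runs, fpr_target = 0.05) {
  stopifnot(length(runs) >= 1, !is.null(names(runs)))
  cfp <- vapply(names(runs), function(pl) {
    r <- runs[[pl]]
    roc <- roc_curve(r$detections, r$truth)
    op <- roc_operating_point(roc, fpr_target)
    m <- strict_match(r$detections$index[r$detections$score >= op$threshold], r$truth)
    as.numeric(m$Cfp)
  }, 0)
  tot <- sum(cfp)
  data.frame(placement = names(runs), cfp = cfp,
             share = if (tot > 0) cfp / tot else rep(0, length(cfp)),
             row.names = NULL)
}

#' Context-delta report
#'
#' Given a named list of per-context metric values (accuracies for walk
#' detection, or TPR at a fixed FPR for step counting) and the name of the
#' baseline entry, reports each context's delta against the baseline.
#' Entries holding several values (one per placement, rate or window) are
#' reported as a [min, max] delta range, the shape used for context-impact
#' tables.
#'
#' @param results named list; each element a numeric scalar or named vector.
#' @param baseline name of the baseline element (a scalar).
#' @return data.frame(context, value_min, value_max, delta_min, delta_max).
#' @export
context_report <- function(results, baseline = "baseline") {
  if (!baseline %in% names(results)) stop("missing baseline entry '", baseline, "'")
  base <- unname(results[[baseline]])
  stopifnot(length(base) == 1, is.finite(base))
  rows <- lapply(names(results), function(nm) {
    v <- results[[nm]]
    data.frame(context = nm,
               value_min = min(v), value_max = max(v),
               delta_min = min(v) - base, delta_max = max(v) - base)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- base
  out
}
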