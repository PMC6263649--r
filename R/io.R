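## File formats.  Everything is header-ed CSV (plus YAML run configs):
## recordings (time_s, ax, ay, az), activity labels (start_s, end_s,
## activity), gait-cycle annotations (cycle_start_idx, cycle_end_idx;
## 0-based, half-open), metric reports and ROC tables.  write_* and read_*
## are exact inverses up to numeric printing precision (15 significant
## digits, well inside the 1e-9 round-trip contract).

fmt_num <- function(x) formatC(x, digits = 15, format = "g")

#' Read a tri-axial recording from CSV
#'
#' Validates the file contract: columns time_s, ax, ay, az; strictly
#' increasing time; median inter-sample interval within 5% of
#' 1/declared_rate.  A sibling label file (same path with suffix
#' `_labels.csv`), if present or given, is attached.
#'
#' @param path CSV file path.
#' @param declared_rate_hz declared sampling rate.
#' @param labels_path optional label CSV; NULL tries the sibling file.
#' @param units acceleration units tag (default "g").
#' @return an `accel_recording`.
#' @export
read_recording <- function(path, declared_rate_hz, labels_path = NULL,
                           units = "g") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(utils::read.csv(path), error = function(e)
    stop("parse error in ", path, ": ", conditionMessage(e)))
  need <- c("time_s", "ax", "ay", "az")
  if (!all(need %in% names(df)))
    stop("recording file must have columns ", paste(need, collapse = ", "))
  for (cn in need) if (!is.numeric(df[[cn]]))
    stop("parse error: non-numeric values in column ", cn,
         " (first bad row ", which(!grepl("^[-0-9.eE+]+$", as.character(df[[cn]])))[1], ")")
  dt <- diff(df$time_s)
  if (any(dt <= 0))
    stop("parse error: time not strictly increasing at row ", which(dt <= 0)[1] + 1L)
  med <- stats::median(dt)
  if (abs(med - 1 / declared_rate_hz) * declared_rate_hz > 0.05)
    stop(sprintf("rate error: median interval %.6g s vs declared %g Hz (> 5%% off)",
                 med, declared_rate_hz))
  labels <- NULL
  if (is.null(labels_path)) {
    cand <- sub("\\.csv$", "_labels.csv", path)
    if (file.exists(cand)) labels_path <- cand
  }
  if (!is.null(labels_path)) labels <- read_labels(labels_path)
  new_recording(df$time_s, df$ax, df$ay, df$az, declared_rate_hz,
                units = units, labels = labels)
}

#' Write a recording (and its labels) to CSV
#'
#' @param recording an `accel_recording`.
#' @param path output CSV path; labels, if any, go to the sibling
#'   `_labels.csv`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "accel_recording"))
  df <- data.frame(time_s = fmt_num(recording$time_s),
                   ax = fmt_num(recording$ax), ay = fmt_num(recording$ay),
                   az = fmt_num(recording$az))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(recording$labels))
    write_labels(recording$labels, sub("\\.csv$", "_labels.csv", path))
  invisible(path)
}

#' Read activity label segments from CSV
#' @param path CSV with columns start_s, end_s, activity.
#' @return validated data.frame.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "activity")
  if (!all(need %in% names(df))) stop("label file must have columns ",
                                      paste(need, collapse = ", "))
  if (any(!df$activity %in% ACTIVITIES))
    stop("unknown activity: ", setdiff(df$activity, ACTIVITIES)[1])
  if (any(df$start_s >= df$end_s)) stop("label segments must have start_s < end_s")
  df <- df[order(df$start_s), ]
  if (nrow(df) > 1 && any(df$start_s[-1] < df$end_s[-nrow(df)] - 1e-9))
    stop("label segments overlap")
  rownames(df) <- NULL
  df
}

#' @rdname read_labels
#' @param labels data.frame(start_s, end_s, activity).
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(data.frame(start_s = fmt_num(labels$start_s),
                              end_s = fmt_num(labels$end_s),
                              activity = labels$activity),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gait-cycle annotations from CSV
#'
#' Rows of (cycle_start_idx, cycle_end_idx): 0-based, half-open, ordered,
#' non-overlapping.  The row count is the ground-truth step count Cgt.
#'
#' @param path CSV path.
#' @param n_samples recording length, to validate the ranges (optional).
#' @return a `gait_truth`.
#' @export
read_gait_annotations <- function(path, n_samples = NULL) {
  df <- utils::read.csv(path)
  need <- c("cycle_start_idx", "cycle_end_idx")
  if (!all(need %in% names(df))) stop("annotation file must have columns ",
                                      paste(need, collapse = ", "))
  if (any(df$cycle_start_idx >= df$cycle_end_idx)) stop("cycles must be non-empty")
  if (nrow(df) > 1 && any(df$cycle_start_idx[-1] < df$cycle_end_idx[-nrow(df)]))
    stop("cycles must be ordered and non-overlapping")
  if (!is.null(n_samples) && any(df$cycle_end_idx > n_samples))
    stop("cycle extends past the recording")
  structure(list(cycles = df, n_cycles = nrow(df)), class = "gait_truth")
}

#' @rdname read_gait_annotations
#' @param truth a `gait_truth`.
#' @export
write_gait_annotations <- function(truth, path) {
  utils::write.csv(truth$cycles[, c("cycle_start_idx", "cycle_end_idx")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a metric report
#'
#' One CSV record per algorithm-context evaluation: counts (Ctp, Cfp, Cgt,
#' Cest) and the derived TPR, FPR and loose error, with algorithm and
#' context tags.  [read_metrics()] inverts [write_metrics()].
#'
#' @param metrics a `strict_sc_metrics`, or a (possibly named) list of
#'   them, or an empty list (header-only report).
#' @param path output CSV.
#' @param algo,context tags recycled over records.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path, algo = NA_character_,
                          context = NA_character_) {
  if (inherits(metrics, "strict_sc_metrics")) metrics <- list(metrics)
  rows <- lapply(seq_along(metrics), function(i) {
    m <- metrics[[i]]
    data.frame(algo = rep_len(algo, length(metrics))[i],
               context = rep_len(context, length(metrics))[i],
               Ctp = m$Ctp, Cfp = m$Cfp, Cgt = m$Cgt, Cest = m$Cest,
               tpr = m$tpr, fpr = m$fpr, loose_pct = m$loose_pct)
  })
  hdr <- data.frame(algo = character(), context = character(),
                    Ctp = integer(), Cfp = integer(), Cgt = integer(),
                    Cest = integer(), tpr = numeric(), fpr = numeric(),
                    loose_pct = numeric())
  df <- if (length(rows)) do.call(rbind, rows) else hdr
  num <- c("tpr", "fpr", "loose_pct")
  for (cn in num) df[[cn]] <- fmt_num(df[[cn]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  df <- utils::read.csv(path)
  lapply(seq_len(nrow(df)), function(i) {
    structure(list(Ctp = df$Ctp[i], Cfp = df$Cfp[i], Cgt = df$Cgt[i],
                   Cest = df$Cest[i], misses = df$Cgt[i] - df$Ctp[i],
                   tpr = df$tpr[i], fpr = df$fpr[i],
                   loose_pct = df$loose_pct[i]),
              class = "strict_sc_metrics")
  })
}

#' Write / read an ROC table
#' @param roc an `sc_roc` data.frame.
#' @param path CSV path.
#' @return `path` (write) / the `sc_roc` (read).
#' @export
write_roc <- function(roc, path) {
  df <- data.frame(threshold = fmt_num(roc$threshold),
                   fpr = fmt_num(roc$fpr), tpr = fmt_num(roc$tpr))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_roc
#' @export
read_roc <- function(path) {
  df <- utils::read.csv(path)
  structure(df[, c("threshold", "fpr", "tpr")],
            class = c("sc_roc", "data.frame"))
}

#' Run configuration
#'
#' Holds the evaluation context (orientation/personalization knowledge,
#' sampling rate, window size, placement), the algorithm and its
#' parameters, simulator parameters and the seed.  All randomness of a run
#' flows from this one seed.
#'
#' @param context list(IO_known, IP_known, R, W, L).
#' @param algo algorithm name.
#' @param algo_params named list of algorithm parameters.
#' @param sim_params named list of simulator parameters.
#' @param seed non-negative integer seed.
#' @param output_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(context = list(IO_known = FALSE, IP_known = FALSE,
                                      R = 200, W = 3, L = NA),
                       algo = "stft", algo_params = list(),
                       sim_params = list(), seed = 1L, output_dir = ".") {
  stopifnot(context$R >= 5, context$R <= 200,
            context$W >= 1.5, context$W <= 6,
            is.na(context$L) || context$L %in% PLACEMENTS,
            seed >= 0)
  structure(list(context = context, algo = algo, algo_params = algo_params,
                 sim_params = sim_params, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
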