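make_truth <- function(starts, ends) {
  structure(list(cycles = data.frame(cycle_start_idx = starts,
                                     cycle_end_idx = ends),
                 n_cycles = length(starts)),
            class = "gait_truth")
}

test_that("strict matching scores forced configurations exactly", {
  truth <- make_truth(c(0, 100, 200, 300), c(100, 200, 300, 400))
  m <- strict_match(c(10, 50, 150, 350), truth)     # per-cycle events 2,1,0,1
  expect_equal(m$Ctp, 3L); expect_equal(m$Cfp, 1L)
  expect_equal(m$tpr, 0.75); expect_equal(m$fpr, 0.25)
  perfect <- strict_match(c(10, 150, 250, 350), truth)
  expect_equal(perfect$tpr, 1); expect_equal(perfect$fpr, 0)
  outside <- strict_match(c(10, 150, 250, 350, 500), truth)
  expect_equal(outside$Cfp, 1L)                      # event past all cycles
  expect_error(strict_match(1:3, make_truth(integer(0), integer(0))), "Cgt")
})

test_that("strict matching agrees exactly with the per-cycle oracle on random cases", {
  set.seed(61)
  for (i in 1:1000) {
    n_cyc <- sample(1:15, 1)
    bounds <- sort(sample(0:500, n_cyc + 1))
    # random gaps between cycles
    starts <- bounds[-length(bounds)]
    ends <- pmin(starts + sample(1:30, n_cyc, replace = TRUE), bounds[-1])
    keep <- ends > starts
    if (!any(keep)) next
    truth <- make_truth(starts[keep], ends[keep])
    events <- sort(sample(0:520, sample(0:25, 1)))
    m <- strict_match(events, truth)
    o <- oracle_strict_match(events, truth$cycles)
    expect_identical(m$Ctp, o$Ctp, info = paste("case", i))
    expect_identical(m$Cfp, o$Cfp, info = paste("case", i))
    # conservation: Ctp + misses = Cgt
    expect_identical(m$Ctp + m$misses, m$Cgt)
  }
})

test_that("count errors follow the loose and strict definitions", {
  expect_equal(sc_error(100, 100)$relative, 0)
  e <- sc_error(95, 100)
  expect_equal(e$relative, 0.05)
  expect_equal(e$loose_pct, -5)
  expect_equal(sc_error(210, 100)$relative, 1.1)    # can exceed 1
})

test_that("ROC curves are monotone with threshold extremes at the corners", {
  sim <- clean_walk(60, 100, seed = 62, noise_sd = 0.05)
  det <- count_steps(sim$recording, "ptm")
  roc <- roc_curve(det, sim$truth)
  expect_equal(roc$tpr[1], 0); expect_equal(roc$fpr[1], 0)  # above max score
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$threshold) < 0))
  m_all <- strict_match(det, sim$truth)
  expect_equal(roc$tpr[nrow(roc)], m_all$tpr)
})

test_that("operating-point selection picks the FPR nearest the target, ties low", {
  roc <- structure(data.frame(threshold = c(3, 2, 1),
                              fpr = c(0.01, 0.05, 0.09),
                              tpr = c(0.5, 0.8, 0.9)),
                   class = c("sc_roc", "data.frame"))
  expect_equal(roc_operating_point(roc, 0.05)$tpr, 0.8)
  expect_equal(roc_operating_point(roc, 0.03)$tpr, 0.5)   # tie -> lower FPR
})

test_that("error sources distribute false positives across placements", {
  truth <- make_truth(seq(0, 5900, 100), seq(100, 6000, 100))   # 60 cycles
  mkdet <- function(idx) gaitbench:::new_step_detections(
    idx, rep(1, length(idx)), 100, "synthetic")
  perfect <- seq(50, 5950, 100)
  # all false positives come from one placement -> its share is 1
  runs <- list(Foot = list(detections = mkdet(perfect), truth = truth),
               Hand = list(detections = mkdet(sort(c(perfect, perfect[1:10] + 20))),
                           truth = truth))
  es <- error_sources(runs, fpr_target = 1)      # operating point keeps all events
  expect_equal(sum(es$share), 1, tolerance = 1e-12)
  expect_equal(es$share[es$placement == "Hand"], 1)
  expect_equal(es$share[es$placement == "Foot"], 0)
  # uniform false positives -> equal shares
  runs4 <- lapply(c(a = 1, b = 2, c = 3, d = 4), function(i)
    list(detections = mkdet(sort(c(perfect, perfect[1:5] + 20))), truth = truth))
  es4 <- error_sources(runs4, fpr_target = 1)
  expect_equal(es4$share, rep(0.25, 4))
})

test_that("context deltas are zero for identical runs and ranges cover axes", {
  rep <- context_report(list(baseline = 0.9, same = 0.9,
                             placement = c(A = 0.85, B = 0.95)), "baseline")
  expect_equal(rep$delta_min[rep$context == "same"], 0)
  expect_equal(rep$delta_max[rep$context == "same"], 0)
  expect_equal(rep$delta_min[rep$context == "placement"], -0.05)
  expect_equal(rep$delta_max[rep$context == "placement"], 0.05)
  expect_error(context_report(list(a = 1), "baseline"), "baseline")
})
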