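test_that("single pulses and tie-breaking behave as specified", {
  x <- c(numeric(50), seq(0, 1, 0.1), seq(0.9, 0, -0.1), numeric(50))
  det <- detect_peaks(x, 100, min_prominence = 0)
  expect_equal(nrow(det), 1L)
  expect_equal(det$index, which.max(x) - 1L)
  # two equal peaks 0.2 s apart with 0.5 s minimum distance: keep the earlier
  y <- numeric(200)
  y[c(100, 120)] <- 1
  det2 <- detect_peaks(y, 100, min_distance_s = 0.5, min_prominence = 0)
  expect_equal(det2$index, 99L)
})

test_that("peak pruning agrees exactly with the exhaustive oracle on fuzz signals", {
  set.seed(51)
  for (i in 1:300) {
    n <- sample(30:150, 1)
    x <- round(rnorm(n), sample(1:2, 1))        # plateaus and tied heights
    md <- sample(c(2, 5, 10), 1) / 100
    mh <- sample(c(-Inf, 0, 0.5), 1)
    mp <- sample(c(0, 0.2), 1)
    th <- sample(c(-Inf, 0.3), 1)
    det <- detect_peaks(x, 100, min_height = mh, min_distance_s = md,
                        min_prominence = mp, threshold = th)
    expect_identical(det$index,
                     oracle_detect_peaks(x, 100, mh, md, mp, th),
                     info = paste("case", i))
  }
})

test_that("raising the decision threshold never increases the event count", {
  set.seed(52)
  sim <- clean_walk(40, 100, seed = 52, noise_sd = 0.05)
  d <- count_steps(sim$recording, "stft")
  ths <- sort(unique(d$score))
  counts <- vapply(ths, function(t) sum(d$score >= t), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("the state machine emits one event per qualifying oscillation", {
  t <- (0:1999) / 100
  x <- sin(2 * pi * 1 * t)
  cfg <- fsm_config(0.5, 0.2, -0.2, -0.5)
  det <- fsm_count(x, cfg, 100)
  expect_equal(nrow(det), 20L)       # one event per period
  expect_equal(nrow(fsm_count(numeric(500), cfg, 100)), 0L)
  expect_equal(nrow(fsm_count(0.4 * x, cfg, 100)), 0L)   # never reaches t1
  expect_error(fsm_config(0.5, 0.6, -0.2, -0.5), "t1 > t2")
})

test_that("grid search reaches a perfect operating point on clean data and generalizes", {
  sim <- clean_walk(60, 100, seed = 53)
  xn <- normalize_variance(magnitude(sim$recording))
  cfg <- fsm_grid_search(xn, sim$truth, 100)
  m <- strict_match(fsm_count(xn, cfg, 100), sim$truth)
  expect_equal(m$tpr, 1)
  expect_equal(m$fpr, 0)
  # one-point grid returns that point
  g1 <- data.frame(t1 = 1, t2 = 0, t3 = -0.1, t4 = -1)
  expect_equal(unclass(fsm_grid_search(xn, sim$truth, 100, grid = g1))[1:4],
               list(t1 = 1, t2 = 0, t3 = -0.1, t4 = -1))
  # train/test split of one long bout: test TPR within 5 points
  sim2 <- clean_walk(120, 100, seed = 54, noise_sd = 0.05)
  xn2 <- normalize_variance(magnitude(sim2$recording))
  half <- length(xn2) %/% 2
  tr_cyc <- sim2$truth$cycles[sim2$truth$cycles$cycle_end_idx <= half, ]
  te_cyc <- sim2$truth$cycles[sim2$truth$cycles$cycle_start_idx >= half, ]
  te_cyc[] <- te_cyc - half
  tr_truth <- structure(list(cycles = tr_cyc, n_cycles = nrow(tr_cyc)), class = "gait_truth")
  te_truth <- structure(list(cycles = te_cyc, n_cycles = nrow(te_cyc)), class = "gait_truth")
  cfg2 <- fsm_grid_search(xn2[1:half], tr_truth, 100)
  tr_tpr <- strict_match(fsm_count(xn2[1:half], cfg2, 100), tr_truth)$tpr
  te_tpr <- strict_match(fsm_count(xn2[(half + 1):length(xn2)], cfg2, 100), te_truth)$tpr
  expect_lte(abs(tr_tpr - te_tpr), 0.05 + 1e-9)
})

test_that("the Pan-Tompkins chain counts impulses and ignores constants", {
  x <- numeric(60 * 200)
  x[round((0:59 + 0.5) * 200) + 1] <- 1
  expect_equal(nrow(ptm_count(x, 200)), 60L)
  expect_equal(nrow(ptm_count(rep(1, 5000), 200)), 0L)
  # squaring homogeneity: doubling the amplitude quadruples scores,
  # indices unchanged
  sim <- clean_walk(30, 100, seed = 55, noise_sd = 0)
  m <- magnitude(sim$recording)
  d1 <- ptm_count(m, 100)
  d2 <- ptm_count(2 * m, 100)
  expect_identical(d1$index, d2$index)
  expect_equal(d2$score, 4 * d1$score, tolerance = 1e-9)
  expect_error(ptm_count(numeric(100), 200), "transient")
})

test_that("spectral sparsification keeps the stopping-rule energy and finds tone periods", {
  set.seed(56)
  t <- (0:5999) / 100
  x <- sin(2 * pi * 1 * t) + 0.05 * rnorm(6000)
  xn <- normalize_variance(x)
  det <- stft_count(xn, 100)
  expect_equal(nrow(det), 60L, tolerance = 0.04)
  expect_error(stft_count(numeric(1000), 100), "all-zero|degenerate")
  # stopping rule: kept energy is in [0.2, 0.2 + largest pair share]
  X <- fft(xn); e <- Mod(X)^2
  n <- length(xn)
  half <- seq_len(n %/% 2 + 1)
  pair <- ifelse(half == 1, 1, n - half + 2)
  pe <- e[half] + ifelse(pair != half, e[pair], 0)
  ord <- order(-pe)
  csum <- cumsum(pe[ord]) / sum(e)
  k <- which(csum >= 0.2)[1]
  expect_gte(csum[k], 0.2)
  expect_lte(csum[k], 0.2 + max(pe) / sum(e))
})

test_that("wavelet counters pick the subband matching their levels", {
  sim <- clean_walk(60, 200, seed = 57)
  m <- magnitude(sim$recording)
  d_slow <- dwt_count(m, 200, "dwt")
  m_slow <- strict_match(d_slow, sim$truth)
  expect_gte(m_slow$tpr, 0.95)
  expect_equal(nrow(dwt_count(numeric(4096) + 1, 200, "dwt")), 0L)
})

test_that("Group II event streams are halved to one step per gait cycle", {
  p <- gait_params(stride_frequency_hz = 1, noise_sd = 0,
                   orientation = "identity", placement = "UpPocket")
  sim <- simulate_walk(p, 60, 200, seed = 58)
  det <- count_steps(sim$recording, "stft")
  m <- strict_match(det, sim$truth)
  expect_equal(m$Cest, 60L, tolerance = 0.05)
  expect_gte(m$tpr, 0.9)
  expect_lte(m$fpr, 0.1)
})
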