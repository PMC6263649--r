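test_that("threshold fitting separates separable classes at the midpoint", {
  m <- thr_fit(c(10, 20, 1, 2), c("walk", "walk", "nonwalk", "nonwalk"))
  expect_equal(m$threshold, 6)             # midpoint of the optimal gap (2, 10)
  expect_equal(m$train_accuracy, 1)
  m2 <- thr_fit(c(5, 1), c("walk", "nonwalk"))
  expect_equal(m2$threshold, 3)
  expect_error(thr_fit(1:4, rep("walk", 4)), "both classes")
})

test_that("threshold fitting matches the brute-force best split on random data", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    stat <- round(rnorm(n), sample(0:2, 1))   # rounding induces ties
    walk <- runif(n) < 0.5
    if (all(walk) || !any(walk)) next
    m <- thr_fit(stat, walk)
    o <- oracle_best_split(stat, walk)
    expect_identical(m$train_accuracy, o$accuracy)
    expect_identical(m$threshold, o$threshold)
  }
})

test_that("band energy classifies tones in and out of the walk band", {
  t <- (0:599) / 200
  fr <- frame_signal(numeric(600), 200, 3)
  e_in <- frame_band_energy(sin(2 * pi * 1 * t), fr, 200)
  e_out <- frame_band_energy(sin(2 * pi * 5 * t), fr, 200)
  e_zero <- frame_band_energy(numeric(600), fr, 200)
  expect_gt(e_in, 100 * e_out)
  expect_equal(e_zero, 0)
  m <- thr_fit(c(e_in, e_out, e_zero), c("walk", "nonwalk", "nonwalk"), "stft")
  expect_true(predict(m, e_in))
  expect_false(any(predict(m, c(e_out, e_zero))))
  expect_error(frame_band_energy(numeric(600), fr, 3), "Nyquist")
})

test_that("wavelet detail energy classifies tones by subband", {
  t <- (0:5999) / 200
  x_walk <- sin(2 * pi * 1 * t)    # inside levels 7-8
  x_fast <- sin(2 * pi * 20 * t)
  fr <- frame_signal(x_walk, 200, 3)
  e_walk <- frame_dwt_energy(x_walk, fr, 200)
  e_fast <- frame_dwt_energy(x_fast, fr, 200)
  expect_gt(min(e_walk), 10 * max(e_fast))
  e_zero <- frame_dwt_energy(numeric(6000), fr, 200)
  expect_true(all(e_zero < 1e-20))
})

test_that("cross-validated classifiers separate well-separated clouds", {
  set.seed(42)
  n <- 100
  x <- rbind(matrix(rnorm(n * 8, 0), n, 8), matrix(rnorm(n * 8, 10), n, 8))
  y <- factor(rep(c("walk", "nonwalk"), each = n), levels = c("walk", "nonwalk"))
  for (algo in c("knn", "svm")) {
    expect_gte(wd_evaluate(x, y, algo, folds = 10, seed = 1)$accuracy, 0.99)
  }
})

test_that("label permutation drives cross-validated accuracy to chance", {
  set.seed(43)
  n <- 150
  x <- matrix(rnorm(2 * n * 8), 2 * n, 8)
  y <- factor(sample(rep(c("walk", "nonwalk"), n)), levels = c("walk", "nonwalk"))
  acc <- wd_evaluate(x, y, "knn", folds = 10, seed = 2)$accuracy
  expect_gt(acc, 0.35)
  expect_lt(acc, 0.65)
})

test_that("threshold detectors are rotation invariant through the magnitude", {
  sim <- clean_walk(30, 100, seed = 44, noise_sd = 0.02)
  rot <- { set.seed(45); random_rotation() }
  m0 <- magnitude(sim$recording)
  m1 <- magnitude(rotate_recording(sim$recording, rot))
  fr <- frame_signal(m0, 100, 3)
  expect_lt(max(abs(frame_band_energy(m0, fr, 100) - frame_band_energy(m1, fr, 100))), 1e-9)
  expect_lt(max(abs(frame_variance(m0, fr) - frame_variance(m1, fr))), 1e-9)
})

test_that("frame-level error counting matches its definition", {
  truth <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(wd_error(truth, truth)$error, 0)
  expect_equal(wd_error(!truth, truth)$error, 4)
  expect_equal(wd_error(c(TRUE, FALSE, FALSE, FALSE), truth)$accuracy, 0.75)
  set.seed(46)
  acc <- wd_error(runif(1000) < 0.5, rep(c(TRUE, FALSE), 500))$accuracy
  expect_gt(acc, 0.45); expect_lt(acc, 0.55)
})
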