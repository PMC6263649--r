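test_that("magnitude is the per-sample Euclidean norm", {
  rec <- gaitbench:::new_recording(0:1 / 100, c(3, 0), c(4, 0), c(0, 1), 100)
  expect_equal(as.numeric(magnitude(rec)), c(5, 1))
})

test_that("low-pass keeps DC and the passband, attenuates the stopband", {
  expect_lt(max(abs(lowpass(rep(2.5, 500), 15, 200) - 2.5)), 1e-9)
  t <- seq(0, 10, by = 1 / 200)
  amp <- function(f) {
    y <- lowpass(sin(2 * pi * f * t), 15, 200)
    max(abs(y[500:1500]))
  }
  expect_gt(amp(1), 0.95)                   # 1 Hz within 5%
  expect_lt(amp(50), 10^(-20 / 20))          # 50 Hz attenuated >= 20 dB
})

test_that("cutoffs at or above Nyquist are clipped with a warning", {
  expect_warning(y <- lowpass(rnorm(200), 50, 40), "clipped")
  expect_length(y, 200)
})

test_that("framing matches the canonical 3 s / 0.5 s layout and the one-sixth rule", {
  x <- numeric(60 * 200)
  fr <- frame_signal(x, 200, window_s = 3, overlap_s = 0.5)
  expect_equal(nrow(fr), 23L)               # floor((12000-600)/500)+1
  fr1 <- frame_signal(numeric(600), 200, window_s = 3)
  expect_equal(nrow(fr1), 1L)
  fr6 <- frame_signal(numeric(12 * 200), 200, window_s = 6)
  expect_equal(attr(fr6, "overlap_s"), 1)   # 6 s window -> 1 s overlap
  expect_error(frame_signal(numeric(100), 200, window_s = 3), "longer")
})

test_that("frame counts agree with direct enumeration over random layouts", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(500:5000, 1)
    w <- sample(50:400, 1)
    ov <- sample(0:(w - 1), 1)
    if (w > n) next
    fr <- frame_signal(numeric(n), 100, w / 100, ov / 100)
    expect_identical(nrow(fr), oracle_frame_count(n, w, w - ov))
  }
})

test_that("frame labels are majority labels with ties broken against walk", {
  x <- numeric(1000)
  labels <- data.frame(start_s = c(0, 5), end_s = c(5, 10),
                       activity = c("walk", "stand"))
  fr <- frame_signal(x, 100, window_s = 2, overlap_s = 1, labels = labels)
  expect_equal(fr$label[1], "walk")                      # frame 0-2 s
  mid <- which(fr$start_idx == 400)                      # 4-6 s: 1 s walk, 1 s stand
  expect_equal(fr$label[mid], "stand")
})

test_that("variance normalization is an affine invariant with unit output variance", {
  set.seed(22)
  x <- rnorm(500, mean = 3, sd = 2)
  z <- normalize_variance(x)
  expect_lt(abs(var(z) - 1), 1e-9)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(max(abs(normalize_variance(0.3 * x + 7) - z)), 1e-9)
  expect_error(normalize_variance(rep(1, 100)), "degenerate")
})

test_that("resampling preserves tone amplitude and duration", {
  rec <- clean_walk(20, 200, seed = 9)$recording
  expect_identical(resample_recording(rec, 200), rec)
  r50 <- resample_recording(rec, 50)
  expect_equal(length(r50$ax), 20 * 50, tolerance = 1e-9)
  t <- seq(0, 60, by = 1 / 200)
  tone <- gaitbench:::new_recording(t, sin(2 * pi * t), numeric(length(t)),
                                    numeric(length(t)), 200)
  r20 <- resample_recording(tone, 20)
  mid <- 100:(length(r20$ax) - 100)
  expect_lt(abs(max(abs(r20$ax[mid])) - 1), 0.02)
  expect_error(resample_recording(rec, 400), "upsampling")
})

test_that("low-pass is idempotent on already band-limited signals", {
  t <- seq(0, 10, by = 1 / 200)
  x <- sin(2 * pi * 2 * t)
  once <- lowpass(x, 15, 200)
  twice <- lowpass(once, 15, 200)
  expect_lt(max(abs(twice - once)), 1e-3)   # only passband ripple remains
})
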