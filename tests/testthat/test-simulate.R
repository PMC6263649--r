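test_that("zero-noise bout has exactly duration x cadence gait cycles", {
  sim <- clean_walk(60, 200, seed = 1, f = 1.0)
  expect_equal(sim$truth$n_cycles, 60L)
  expect_equal(nrow(sim$truth$cycles), 60L)
  sim2 <- clean_walk(45, 100, seed = 1, f = 1.1)
  expect_equal(sim2$truth$n_cycles, floor(45 * 1.1))
})

test_that("the same seed reproduces the recording exactly", {
  p <- gait_params(noise_sd = 0.05)
  a <- simulate_walk(p, 10, 100, seed = 7)
  b <- simulate_walk(p, 10, 100, seed = 7)
  expect_identical(a$recording$az, b$recording$az)
  expect_identical(a$truth$cycles, b$truth$cycles)
})

test_that("magnitude is invariant to the sensor orientation", {
  p0 <- gait_params(stride_frequency_hz = 1, noise_sd = 0, orientation = "identity")
  base <- simulate_walk(p0, 10, 100, seed = 3)
  m0 <- magnitude(base$recording)
  set.seed(42)
  for (i in 1:20) {
    rot <- random_rotation()
    expect_lt(max(abs(magnitude(rotate_recording(base$recording, rot)) - m0)), 1e-9)
  }
})

test_that("Group I magnitude peaks at the stride frequency, Group II at twice it", {
  peak_freq <- function(placement) {
    p <- gait_params(stride_frequency_hz = 1, noise_sd = 0,
                     orientation = "identity", placement = placement)
    sim <- simulate_walk(p, 64, 200, seed = 4)
    m <- magnitude(sim$recording) - 1
    sp <- Mod(fft(m))^2
    f <- (seq_along(sp) - 1) * 200 / length(sp)
    sel <- f > 0.2 & f < 5
    f[sel][which.max(sp[sel])]
  }
  bin <- 200 / (64 * 200)
  expect_lt(abs(peak_freq("FrontPocket") - 1), bin + 1e-9)
  expect_lt(abs(peak_freq("UpPocket") - 2), bin + 1e-9)
})

test_that("static activities read a constant 1 g at zero noise", {
  rec <- simulate_activity("stand", 5, 100, seed = 1, noise_sd = 0)
  expect_lt(max(abs(magnitude(rec) - 1)), 1e-12)
})

test_that("running concentrates less energy in the walk band than walking", {
  run <- simulate_activity("run", 30, 200, seed = 5, noise_sd = 0,
                           amplitude_scale = 1, orientation = "identity")
  p <- gait_params(stride_frequency_hz = 1, harmonics = c(0.6, 0.25, 0.1),
                   noise_sd = 0, orientation = "identity")
  walk <- simulate_walk(p, 30, 200, seed = 5)$recording
  band <- function(rec) {
    m <- magnitude(rec)
    fr <- frame_signal(m, 200, window_s = 30, overlap_s = 0)
    frame_band_energy(m, fr, 200)
  }
  expect_lt(band(run), band(walk))
})

test_that("riding produces a lower-variance magnitude than walking", {
  ride <- simulate_activity("ride", 30, 200, seed = 6)
  walk <- clean_walk(30, 200, seed = 6, noise_sd = 0.02)$recording
  expect_lt(var(magnitude(ride)), var(magnitude(walk)))
})

test_that("sessions concatenate with exact labels and pooled cycle counts", {
  p <- gait_params(stride_frequency_hz = 1, noise_sd = 0)
  sim <- compose_session(data.frame(activity = c("walk", "stand", "walk"),
                                    duration_s = c(30, 10, 20)),
                         rate_hz = 100, seed = 8, params = p)
  expect_equal(nrow(sim$recording$labels), 3L)
  expect_equal(sim$recording$labels$activity, c("walk", "stand", "walk"))
  expect_equal(sim$truth$n_cycles, 30L + 20L)
  expect_equal(length(sim$recording$ax), 60 * 100)
  # cycle annotations stay inside their walking bouts
  expect_true(all(sim$truth$cycles$cycle_end_idx <= 60 * 100))
  # permuting the plan permutes segments, total length invariant
  sim2 <- compose_session(data.frame(activity = c("stand", "walk", "walk"),
                                     duration_s = c(10, 30, 20)),
                          rate_hz = 100, seed = 8, params = p)
  expect_equal(length(sim2$recording$ax), length(sim$recording$ax))
  expect_equal(sim2$recording$labels$activity[1], "stand")
})

test_that("placement groups follow the two-period taxonomy", {
  expect_equal(placement_group("Foot"), "I")
  expect_equal(placement_group("UpPocket"), "II")
  expect_equal(placement_group("Hand"), "I")
  expect_equal(placement_group("Hand", hand_group = "II"), "II")
  expect_error(placement_group("Wrist"))
})

test_that("degenerate simulation requests error out", {
  expect_error(simulate_walk(gait_params(stride_frequency_hz = 1), 2, 200, 1),
               "fewer than 3")
  expect_error(simulate_walk(gait_params(stride_frequency_hz = 3), 10, 5, 1),
               "Nyquist")
  expect_error(simulate_activity("juggle", 10, 100, 1), "unknown activity")
})
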