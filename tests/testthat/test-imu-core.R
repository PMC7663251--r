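test_that("pitch and roll match known gravity orientations", {
  # gravity along +Z: level
  expect_equal(pitch_from_accel(0, 0, 1), 0)
  expect_equal(roll_from_accel(0, 0, 1), 0)
  # gravity fully along -X: nose-up 90 degrees
  expect_equal(pitch_from_accel(-1, 0, 0), 90)
  # 30-degree rotation about Y of the unit gravity vector (closed form)
  expect_equal(pitch_from_accel(-0.5, 0, 0.8660254), 30, tolerance = 1e-7)
  # roll quadrants
  expect_equal(roll_from_accel(0, 1, 0), 90)
  expect_equal(roll_from_accel(0, -1, 0), -90)
})

test_that("pitch matches closed-form rotation across -30..+30 degrees", {
  for (theta in seq(-30, 30, by = 5)) {
    a <- c(-sin(theta * pi / 180), 0, cos(theta * pi / 180))
    expect_equal(pitch_from_accel(a[1], a[2], a[3]), theta,
                 tolerance = 1e-12)
  }
})

test_that("pitch is invariant to positive scaling of the input vector", {
  set.seed(11)
  for (i in 1:25) {
    v <- rnorm(3)
    if (all(v == 0)) next
    s <- runif(1, 0.01, 100)
    expect_equal(pitch_from_accel(v[1], v[2], v[3]),
                 pitch_from_accel(s * v[1], s * v[2], s * v[3]),
                 tolerance = 1e-10)
  }
  expect_equal(pitch_from_accel(0, 0, 5), 0)
})

test_that("degenerate samples are rejected", {
  expect_error(pitch_from_accel(0, 0, 0), "zero acceleration")
  expect_error(roll_from_accel(1, 0, 0), "roll undefined")
  expect_error(pitch_from_accel(NA, 0, 1), "finite")
})

test_that("zero-phase smoothing is identity on constants and single taps", {
  tr <- static_trace(12, duration_s = 0.5)
  sm <- smooth_zero_phase(tr, filter_len_s = 0.05)
  expect_equal(sm$ax, tr$ax, tolerance = 1e-12)
  expect_equal(sm$az, tr$az, tolerance = 1e-12)
  # one-sample filter is the identity on any signal
  set.seed(3)
  tr2 <- accel_trace((0:99) / 200, rnorm(100, 0, 0.1), 0, 1)
  expect_equal(smooth_zero_phase(tr2, 1 / 200)$ax, tr2$ax)
  expect_error(smooth_zero_phase(static_trace(0, duration_s = 0.02), 0.05),
               "too short")
})

test_that("double-pass impulse response is the symmetric triangle kernel", {
  # hand-derived: causal 3-tap MA forward then backward = [1,2,3,2,1]/9
  imp <- c(rep(0, 50), 1, rep(0, 49))
  tr <- accel_trace((0:99) / 200, imp, 0, 1)
  sm <- smooth_zero_phase(tr, 3 / 200)
  expect_equal(sum(sm$ax), 1, tolerance = 1e-12)
  expect_equal(sm$ax[49:53], c(1, 2, 3, 2, 1) / 9, tolerance = 1e-12)
  expect_equal(sm$ax[c(1:48, 54:100)], rep(0, 95), tolerance = 1e-12)
})

test_that("stable window selection matches brute-force minimum-SD search", {
  set.seed(42)
  for (i in 1:100) {
    dur <- runif(1, 0.6, 2)
    tr <- simulate_trace(
      true_pitch_deg = runif(1, -40, 40), duration_s = dur,
      sample_rate_hz = 200, accel_white_sd = runif(1, 0, 0.05),
      sway_amplitude_deg = runif(1, 0, 4), sway_freq_hz = runif(1, 0.1, 1),
      knock = runif(1) < 0.3
    )
    got <- select_stable_window(tr)
    oracle <- brute_force_window(tr)
    expect_equal(got$window_sd_deg, oracle$sd, tolerance = 1e-10)
    expect_equal(got$pitch_deg, oracle$pitch, tolerance = 1e-10)
    expect_equal(got$window_start_s, tr$t[oracle$start])
  }
})

test_that("stable window recovers a noiseless static pose exactly", {
  for (theta in c(-25, -5, 0, 10, 35)) {
    est <- select_stable_window(static_trace(theta, duration_s = 1))
    expect_lt(abs(est$pitch_deg - theta), 1e-9)
    expect_equal(est$window_sd_deg, 0)
    expect_equal(est$window_start_s, 0) # tie-break: earliest window
  }
})

test_that("window bounds, length and mean are internally consistent", {
  set.seed(7)
  tr <- simulate_trace(15, duration_s = 1.5, accel_white_sd = 0.02,
                       sway_amplitude_deg = 1)
  est <- select_stable_window(tr, window_s = 0.3, hop_s = 0.1)
  expect_lt(abs((est$window_end_s - est$window_start_s) - 0.3), 1 / 200 + 1e-12)
  # recompute the mean smoothed pitch over the reported bounds
  sm <- tilt_series(tr)
  idx <- which(sm$t >= est$window_start_s - 1e-9 &
                 sm$t <= est$window_end_s + 1e-9)
  expect_equal(mean(sm$pitch_deg[idx]), est$pitch_deg, tolerance = 1e-10)
})

test_that("recovered pitch is within 1 degree under 0.01 g white noise", {
  set.seed(99)
  for (theta in c(-20, 0, 15)) {
    tr <- simulate_trace(theta, duration_s = 5, accel_white_sd = 0.01)
    est <- select_stable_window(tr)
    expect_lt(abs(est$pitch_deg - theta), 1)
  }
})

test_that("traces shorter than the window are rejected with both durations", {
  tr <- static_trace(5, duration_s = 0.2)
  expect_error(select_stable_window(tr), "0.200.*0.300|0\\.2")
})
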