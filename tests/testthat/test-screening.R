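test_that("tilt change is functional minus nearest preceding standing", {
  sess <- make_session(
    c("standing", "flexed_seated", "standing", "step_up"),
    c(2, -25, 3, 8)
  )
  fs <- tilt_change(sess, "flexed_seated")
  expect_equal(fs$delta_pitch_deg, -27, tolerance = 1e-9)
  expect_equal(fs$baseline_capture, 1)
  su <- tilt_change(sess, "step_up")
  expect_equal(su$delta_pitch_deg, 5, tolerance = 1e-9)
  expect_equal(su$baseline_capture, 3) # nearest standing, not the first
  # identical baseline and functional traces -> zero change
  same <- make_session(c("standing", "flexed_seated"), c(7, 7))
  expect_equal(tilt_change(same, "flexed_seated")$delta_pitch_deg, 0,
               tolerance = 1e-9)
})

test_that("swapping baseline and functional pitches negates the delta", {
  set.seed(5)
  for (i in 1:10) {
    p <- runif(2, -30, 30)
    a <- make_session(c("standing", "flexed_seated"), c(p[1], p[2]))
    b <- make_session(c("standing", "flexed_seated"), c(p[2], p[1]))
    expect_equal(tilt_change(a, "flexed_seated")$delta_pitch_deg,
                 -tilt_change(b, "flexed_seated")$delta_pitch_deg,
                 tolerance = 1e-9)
  }
})

test_that("protocol violations are named", {
  expect_error(
    make_session(c("flexed_seated", "standing"), c(1, 2)),
    "no preceding standing"
  )
  sess <- make_session(c("standing", "flexed_seated"), c(0, -20))
  expect_error(tilt_change(sess, "step_up"), "no step_up capture")
})

test_that("mobility classification honours the 13-degree boundary", {
  expect_true(classify_mobility(15))
  expect_true(classify_mobility(13)) # boundary inclusive
  expect_false(classify_mobility(12.9))
  expect_true(classify_mobility(-14)) # posterior rotation counts too
  expect_false(classify_mobility(5))
  # signed (anterior-only) mode
  expect_false(classify_mobility(-14, mode = "signed"))
  expect_true(classify_mobility(14, mode = "signed"))
  expect_error(classify_mobility(Inf), "finite")
})

test_that("classification is symmetric and monotone in the threshold", {
  xs <- seq(-40, 40, by = 2.5)
  expect_equal(classify_mobility(xs), classify_mobility(-xs))
  for (x in xs) {
    lo <- classify_mobility(x, threshold_deg = 10)
    hi <- classify_mobility(x, threshold_deg = 20)
    expect_false(!lo && hi) # raising the threshold never flips FALSE -> TRUE
  }
})

test_that("session screening ORs positions and reports diagnostics", {
  hi <- make_session(c("standing", "flexed_seated", "standing", "step_up"),
                     c(0, 20, 0, 3))
  rep_hi <- screen_session(hi)
  expect_true(rep_hi$high_mobility)
  expect_equal(rep_hi$results$high_mobility, c(TRUE, FALSE))
  expect_true(all(c("functional_window_sd_deg", "baseline_window_start_s")
                  %in% names(rep_hi$results)))

  lo <- make_session(c("standing", "flexed_seated", "standing", "step_up"),
                     c(0, 5, 0, 2))
  expect_false(screen_session(lo)$high_mobility)

  # flexed-seated-only classifier ignores a large step-up change
  su_only <- make_session(c("standing", "flexed_seated", "standing",
                            "step_up"), c(0, 5, 0, 20))
  expect_true(screen_session(su_only)$high_mobility)
  expect_false(
    screen_session(su_only, positions = "flexed_seated")$high_mobility)
})

test_that("tidy and glance summarise screening reports", {
  sess <- make_session(c("standing", "flexed_seated", "standing", "step_up"),
                       c(1, -18, 1, 4), patient_id = "P9")
  rep <- screen_session(sess)
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$patient_id, c("P9", "P9"))
  gl <- glance(rep)
  expect_equal(gl$high_mobility, TRUE)
  expect_equal(gl$max_abs_delta_deg, 19, tolerance = 1e-6)
})

test_that("anterior sign flip negates deltas", {
  sess <- make_session(c("standing", "flexed_seated"), c(2, 22))
  plus <- tilt_change(sess, "flexed_seated")
  minus <- tilt_change(sess, "flexed_seated", anterior_sign = -1)
  expect_equal(plus$delta_pitch_deg, -minus$delta_pitch_deg,
               tolerance = 1e-9)
})

test_that("short captures warn but still process", {
  captures <- tibble::tibble(
    position = c("standing", "flexed_seated"),
    trace = list(static_trace(0, duration_s = 1),
                 static_trace(15, duration_s = 1))
  )
  expect_warning(session_record(captures), "shorter than the recommended")
})
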