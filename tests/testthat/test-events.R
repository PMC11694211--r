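test_that("movement start is the first sustained threshold crossing", {
  # f_kin = 100 Hz -> sustain window of 4 samples at the 0.04 s default
  vvel <- c(0, 0.005, 0.02, 0.5, 1.0, 1.2, 1.5, 2.0)
  expect_identical(detect_start(vvel, f_kin = 100), 3L)

  expect_error(detect_start(rep(0, 100), f_kin = 100), "no movement")

  # single-sample spike rejected by the sustain window
  spiky <- c(0, 0, 0.5, 0, 0, rep(1, 10))
  expect_identical(detect_start(spiky, f_kin = 100), 6L)
})

test_that("catch is the first zero velocity after the descent from peak height", {
  vpos <- c(0, 1, 2, 3, 2.5, 2, 2, 2)
  vvel <- c(1, 1, 1, 1, -0.5, -0.5, 0, 0)
  got <- detect_catch(vpos, vvel, 1)
  expect_identical(got$ymax_idx, 4L)
  expect_identical(got$catch_idx, 7L)

  expect_error(detect_catch(cumsum(rep(1, 10)), rep(1, 10), 1),
               "no catch detected")
})

test_that("generator catch and takeoff are located on the programmed events", {
  nt <- noiseless_trial()
  ev <- nt$trial$events
  truth <- nt$sim$truth
  expect_lte(abs((ev$catch_idx - 1) / 250 - truth$t_catch) * 250, 2)
  expect_false(is.na(ev$takeoff_idx))
  expect_lt(abs((ev$takeoff_idx - 1) / 1000 - truth$takeoff_time), 0.005)
})

test_that("takeoff detection follows the sustained low-force rule", {
  vgrf <- rep(1.2, 2000)
  vgrf[801:840] <- 0.01                      # 40 ms below threshold
  expect_identical(detect_takeoff(vgrf, 1000), 801L)
  expect_true(is.na(detect_takeoff(rep(0.9, 2000), 1000)))
  vgrf2 <- rep(1.2, 2000); vgrf2[801:810] <- 0.01   # only 10 ms: too short
  expect_true(is.na(detect_takeoff(vgrf2, 1000)))
})

test_that("horizontal extremes read the constructed toward-away-toward path", {
  seg <- function(a, b, n) seq(a, b, length.out = n)
  ap <- c(seg(0, 0.31, 31), seg(0.31, -16.93, 31)[-1],
          seg(-16.93, 9.19, 31)[-1]) / 100
  ev <- list(start_idx = 1L, ymax_idx = 45L, catch_idx = length(ap))
  hx <- horizontal_extremes(ap, ev)
  expect_equal(hx$x1_cm, 0.31, tolerance = 1e-10)
  expect_equal(hx$x2_cm, -16.93, tolerance = 1e-10)
  expect_equal(hx$x3_cm, 9.19, tolerance = 1e-10)

  flat <- rep(0, 91)
  hx0 <- horizontal_extremes(flat, ev)
  expect_equal(c(hx0$x1_cm, hx0$x2_cm, hx0$x3_cm), c(0, 0, 0))

  hxm <- horizontal_extremes(-ap, ev)
  expect_equal(c(hxm$x1_cm, hxm$x2_cm, hxm$x3_cm),
               -c(hx$x1_cm, hx$x2_cm, hx$x3_cm), tolerance = 1e-10)
})

test_that("mirroring the AP axis negates X1, X2, X3 end to end", {
  nt <- noiseless_trial()
  raw <- nt$sim$raw
  mirrored <- raw_trial(raw$subject_id, as.character(raw$condition),
                        raw$trial_index,
                        raw$marker_left %*% diag(c(-1, 1, 1)),
                        raw$marker_right %*% diag(c(-1, 1, 1)),
                        raw$f_kin, raw$plate1, raw$plate2, raw$f_force)
  colnames(mirrored$marker_left) <- colnames(mirrored$marker_right) <-
    c("AP", "ML", "V")
  fm <- process_trial(mirrored, default_subject())$features
  f <- nt$trial$features
  expect_equal(fm$X1, -f$X1, tolerance = 1e-8)
  expect_equal(fm$X2, -f$X2, tolerance = 1e-8)
  expect_equal(fm$X3_DxT, -f$X3_DxT, tolerance = 1e-8)
})

test_that("phase event ordering holds across a 200-trial generated sweep", {
  prm <- cohort_recovery_params(50, seed = 404, noise_sd_pos_mm = 0.5)
  prm2 <- cohort_recovery_params(50, seed = 405, noise_sd_pos_mm = 0.5)
  prm3 <- cohort_recovery_params(50, seed = 406, noise_sd_pos_mm = 0)
  prm4 <- cohort_recovery_params(50, seed = 407, noise_sd_pos_mm = 2)
  for (item in c(prm, prm2, prm3, prm4)) {
    sim <- generate_trial(item$p)
    ev <- process_trial(sim$raw, default_subject())$events
    expect_true(ev$start_idx < ev$ymax_idx)
    expect_true(ev$ymax_idx < ev$catch_idx)
    expect_true(ev$rearmost_idx >= ev$start_idx &&
                  ev$rearmost_idx <= ev$ymax_idx)
    expect_true(ev$foremost_idx >= ev$rearmost_idx &&
                  ev$foremost_idx <= ev$catch_idx)
  }
})

test_that("phase_events enforces its ordering invariants", {
  expect_error(phase_events(10, 5, 20), "start_idx < ymax_idx")
  expect_error(phase_events(10, 50, 100, rearmost_idx = 60),
               "rearmost_idx")
  ev <- phase_events(10, 50, 100, rearmost_idx = 30, foremost_idx = 45)
  expect_s3_class(ev, "phase_events")
})
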