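test_that("derived displacement identities reproduce published condition means", {
  # DL condition means
  dl <- snatch_derived(161.44, 140.75, 0.31, -16.93, 9.19)
  expect_equal(dl$VTR, 20.69, tolerance = 0.01)
  expect_equal(dl$DxV, 17.24, tolerance = 0.01)
  expect_equal(dl$DxT, 9.19, tolerance = 1e-12)
  # RL vertical travel range
  expect_equal(snatch_derived(162.06, 143.18, -0.88, -16.32, 10.5)$VTR,
               18.88, tolerance = 0.01)
  # bCI loop
  expect_equal(snatch_derived(158.47, 141.11, -0.21, -16.82, 6.93)$DxL,
               23.75, tolerance = 0.01)
})

test_that("identities hold exactly on processed trials", {
  prm <- cohort_recovery_params(6, seed = 11, noise_sd_pos_mm = 0.5)
  for (item in prm) {
    f <- process_trial(generate_trial(item$p)$raw, default_subject())$features
    expect_equal(f$VTR, f$Y_max - f$Y_catch, tolerance = 1e-12)
    expect_equal(f$DxV, f$X1 - f$X2, tolerance = 1e-12)
    expect_equal(f$DxL, f$X3_DxT - f$X2, tolerance = 1e-12)
    expect_gt(f$MvT_duration, 0)
  }
})

test_that("noiseless generator trials recover their programmed parameters", {
  prm <- cohort_recovery_params(10, seed = 21, noise_sd_pos_mm = 0)
  for (item in prm) {
    f <- process_trial(generate_trial(item$p)$raw, default_subject())$features
    expect_recovered(f, item$truth, tol_cm = 0.5, tol_v = 0.02)
  }
})

test_that("recovery degrades gracefully and monotonically with marker noise", {
  err_at <- function(noise_mm) {
    prm <- cohort_recovery_params(10, seed = 33, noise_sd_pos_mm = noise_mm)
    mean(vapply(prm, function(item) {
      f <- process_trial(generate_trial(item$p)$raw,
                         default_subject())$features
      abs(f$X2 - item$truth$X2) + abs(f$Y_max - item$truth$Y_max)
    }, numeric(1)))
  }
  e0 <- err_at(0); e2 <- err_at(2); e5 <- err_at(5)
  expect_lt(e0, e2 + 0.05)
  expect_lt(e0, e5)
  # with 2 mm noise everything stays within the relaxed envelope
  prm <- cohort_recovery_params(10, seed = 33, noise_sd_pos_mm = 2)
  for (item in prm) {
    f <- process_trial(generate_trial(item$p)$raw, default_subject())$features
    expect_recovered(f, item$truth, tol_cm = 1, tol_v = 0.05)
  }
})

test_that("kinetic features respect window definitions and flight fallback", {
  nt <- noiseless_trial()
  f <- nt$trial$features
  expect_lt(abs(f$vGRF_max / nt$sim$truth$vgrf_max_bw - 1), 0.02)
  expect_true(f$jump_detected)
  expect_gte(f$RFD_max_all, f$RFD_max_jump)
  expect_gte(f$Power_max_all, f$Power_max_jump)

  # no flight: jump features equal whole-movement features and are flagged
  p <- trial_params(flight = FALSE, noise_sd_pos_mm = 0,
                    noise_sd_force_n = 0, marker_asym_mm = 0)
  tr <- process_trial(generate_trial(p)$raw, default_subject())
  expect_false(tr$features$jump_detected)
  expect_equal(tr$features$vGRF_mean_jump, tr$features$vGRF_mean_all)
  expect_equal(tr$features$RFD_max_jump, tr$features$RFD_max_all)
})

test_that("exactly one of the eight sign patterns is optimal", {
  combos <- expand.grid(x1 = c(-1, 1), x2 = c(-1, 1), x3 = c(-1, 1))
  opt <- mapply(function(a, b, c) classify_path(a, b, c)$is_optimal,
                combos$x1, combos$x2, combos$x3)
  expect_identical(sum(opt), 1L)
  expect_true(classify_path(1, -1, 1)$is_optimal)
  # zero is neither positive nor negative
  expect_false(classify_path(0, -1, 1)$is_optimal)
})

test_that("published condition means classify as reported", {
  expect_true(classify_path(0.31, -16.93, 9.19)$is_optimal)     # DL
  expect_false(classify_path(-0.88, -16.32, 10.5)$is_optimal)   # RL: X1 < 0
  expect_false(classify_path(-0.21, -16.82, 6.93)$is_optimal)   # bCI
  expect_false(classify_path(-0.43, -15.82, 9.39)$is_optimal)   # sCI
})

test_that("subject adherence requires every repetition to be optimal", {
  expect_true(subject_adherence(c(TRUE, TRUE, TRUE)))
  expect_false(subject_adherence(c(TRUE, FALSE, TRUE)))
  expect_error(subject_adherence(logical(0)), "at least one")

  feat <- data.frame(
    subject_id = rep(c("A", "B"), each = 6),
    condition = rep(rep(c("DL", "RL"), each = 3), 2),
    X1 = c(rep(1, 3), rep(-1, 3), c(1, -1, 1), rep(-1, 3)),
    X2 = -10, X3_DxT = 5)
  adh <- path_adherence(feat)
  expect_identical(adh$n_adherent[adh$condition == "DL"], 1L)  # only A
  expect_identical(adh$n_adherent[adh$condition == "RL"], 0L)
})
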