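test_that("trial generation is deterministic per seed", {
  a <- generate_trial(trial_params(seed = 99))
  b <- generate_trial(trial_params(seed = 99))
  expect_identical(a$raw$marker_left, b$raw$marker_left)
  expect_identical(a$raw$plate1, b$raw$plate1)
  c <- generate_trial(trial_params(seed = 100))
  expect_false(identical(a$raw$marker_left, c$raw$marker_left))
})

test_that("static records carry the programmed weight and split", {
  st <- generate_static(body_mass = 80, split = 0.6, noise_sd_force_n = 0,
                        seed = 1)
  tot <- st$plate1[, "V"] + st$plate2[, "V"]
  expect_equal(mean(tot), 80 * 9.81, tolerance = 1e-9)
  expect_equal(mean(st$plate1[, "V"]) / mean(tot), 0.6, tolerance = 1e-9)
  s2 <- generate_static(body_mass = 80, seed = 3)
  s3 <- generate_static(body_mass = 80, seed = 3)
  expect_identical(s2$plate1, s3$plate1)
})

test_that("generated GRF integrates to system weight in the quiet phase", {
  p <- trial_params(seed = 12)
  sim <- generate_trial(p)
  quiet <- 1:800                     # first 0.8 s of the 1 s quiet phase
  tot <- sim$raw$plate1[quiet, "V"] + sim$raw$plate2[quiet, "V"]
  want <- (p$body_mass + p$barbell_mass) * 9.81
  se <- sqrt(2) * p$noise_sd_force_n / sqrt(length(quiet))
  expect_lt(abs(mean(tot) - want), 4 * se)
})

test_that("infeasible trial parameters are rejected with guidance", {
  expect_error(trial_params(duration = 0.4), "duration")
  expect_error(trial_params(y_max_cm = 140, y_catch_cm = 150), "y_max_cm")
  expect_error(trial_params(x2_cm = 5), "x2_cm")
  expect_error(trial_params(duration = 0.9), "need at least")
  expect_error(trial_params(flight_duration = 0.1, taper = 0.08),
               "inconsistent flight window")
  expect_error(trial_params(noise_sd_pos_mm = -1), "noise")
})

test_that("cohorts have the full design and honest ground-truth columns", {
  co <- generate_cohort(cohort_params(n_subjects = 16, seed = 77))
  expect_identical(nrow(co$truth), 192L)
  expect_identical(length(unique(co$truth$subject_id)), 16L)
  expect_true(all(table(co$truth$condition) == 48))
  expect_equal(co$truth$VTR, co$truth$Y_max - co$truth$Y_catch,
               tolerance = 1e-12)
  expect_true(all(co$truth$X2 < pmin(co$truth$X1, co$truth$X3_DxT)))
  expect_true(all(co$truth$MvT_duration > 0.5))
})

test_that("the hierarchical model reproduces the requested ICC", {
  for (icc in c(0.3, 0.5, 0.7)) {
    est <- mean(vapply(1:4, function(r) {
      co <- generate_cohort(cohort_params(n_subjects = 100, icc = icc,
                                          seed = 800 + icc * 10 + r))
      tab <- variable_table(co$truth, "Y_max", "subject_mean")
      cors <- cor(tab)
      mean(cors[upper.tri(cors)])
    }, numeric(1)))
    expect_lt(abs(est - icc), 0.1)
  }
})

test_that("a zero-variance cohort degenerates loudly, not silently", {
  sds0 <- c(y_max_cm = 0, vtr_cm = 0, x1_cm = 0, x2_cm = 0, x3_cm = 0,
            v_max = 0, duration = 0)
  co <- generate_cohort(cohort_params(n_subjects = 5, icc = 0, sds = sds0,
                                      seed = 13))
  tab <- variable_table(co$truth, "V_max", "subject_mean")
  expect_error(rm_anova(tab), "degenerate|identical")
})

test_that("a planted DL-only X1 shift reproduces the qualitative contrast", {
  cp <- cohort_params(n_subjects = 100, seed = 321,
                      shifts = list(x1_cm = c(DL = 2)))
  co <- generate_cohort(cp)
  # the planted shift is recovered in the sample condition means
  m <- tapply(co$truth$X1, co$truth$condition, mean)
  expect_lt(abs((m[["DL"]] - mean(m[c("RL", "bCI", "sCI")])) - 2), 1.2)
  # at the population level only the shifted condition crosses into the
  # optimal toward-away-toward pattern
  mu <- cp$means
  cls_dl <- classify_path(mu[["x1_cm"]] + 2, mu[["x2_cm"]], mu[["x3_cm"]])
  cls_rl <- classify_path(mu[["x1_cm"]], mu[["x2_cm"]], mu[["x3_cm"]])
  expect_true(cls_dl$is_optimal)
  expect_false(cls_rl$is_optimal)
  expect_identical(unname(cls_dl$sign_pattern), c("+", "-", "+"))
  expect_identical(unname(cls_rl$sign_pattern), c("-", "-", "+"))
})
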