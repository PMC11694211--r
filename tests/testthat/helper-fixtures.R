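# Shared fixtures: a default subject, a cached noiseless default trial, and
# cohort-drawn trial parameters for parameter-recovery sweeps.

default_subject <- function() subject_info("S01", 1.78, 75)

.fixture_env <- new.env(parent = emptyenv())

# noiseless default trial processed once and reused across tests
noiseless_trial <- function() {
  if (is.null(.fixture_env$noiseless)) {
    p <- trial_params(noise_sd_pos_mm = 0, noise_sd_force_n = 0,
                      marker_asym_mm = 0)
    sim <- generate_trial(p)
    .fixture_env$noiseless <- list(sim = sim,
                                   trial = process_trial(sim$raw,
                                                         default_subject()))
  }
  .fixture_env$noiseless
}

# one varied trial per subject of a seeded cohort (n_trials = 1, one
# condition per subject), with optional noise override
cohort_recovery_params <- function(n, seed, noise_sd_pos_mm = 0) {
  co <- generate_cohort(cohort_params(n_subjects = n, n_trials = 1,
                                      seed = seed))
  rows <- match(unique(co$truth$subject_id), co$truth$subject_id) +
    (seq_len(n) - 1L) %% 4L
  lapply(rows, function(i)
    list(p = cohort_trial_params(co, i, noise_sd_pos_mm = noise_sd_pos_mm,
                                 noise_sd_force_n =
                                   if (noise_sd_pos_mm > 0) 5 else 0,
                                 seed = 10000 + i),
         truth = co$truth[i, ]))
}

expect_recovered <- function(feat, truth, tol_cm = 0.5, tol_v = 0.02) {
  expect_lt(abs(feat$X1 - truth$X1), tol_cm)
  expect_lt(abs(feat$X2 - truth$X2), tol_cm)
  expect_lt(abs(feat$X3_DxT - truth$X3_DxT), tol_cm)
  expect_lt(abs(feat$Y_max - truth$Y_max), tol_cm)
  expect_lt(abs(feat$Y_catch - truth$Y_catch), tol_cm)
  expect_lt(abs(feat$V_max / truth$V_max - 1), tol_v)
}
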