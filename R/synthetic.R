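#' Ground-truth parameters of one synthetic snatch trial
#'
#' Defines a snatch-shaped trial by its target discrete features, from which
#' [generate_trial] builds marker and force time series with those features
#' as exact ground truth. Default magnitudes are typical of novice power
#' snatches with a 20 kg bar: peak bar height ~161 cm, catch height ~141 cm,
#' peak vertical bar velocity ~3.15 m/s, movement duration ~1.3 s, a bar path
#' that drifts slightly toward the lifter at the end of the pull (X1 ~ +0.3
#' cm), sweeps away during the turnover (X2 ~ -16.5 cm) and returns forward
#' of the start at the catch (X3 ~ +9 cm).
#'
#' The vertical velocity profile is a smoothstep ramp to exactly `v_max`, a
#' short plateau (the explosive second pull) and a ramp back to zero at peak
#' height, followed by a raised-cosine (sin^2) descent pulse down to
#' `y_catch_cm`, so peak velocity, peak height, catch height and catch time
#' are exact by construction. The AP profile is a C2 piecewise-smoothstep
#' curve through labelled control points whose knots are stationary points,
#' so the programmed extremes are the true X1/X2/X3. Both families are smooth
#' enough that the 4 Hz zero-phase trajectory filter leaves the programmed
#' features essentially untouched.
#' Vertical ground reaction force follows a two-mass surrogate: total weight
#' plus coupled bar acceleration (coupling `com_coupling` during the pull and
#' a softer `catch_coupling` during the descent, when the lifter drops under
#' the bar), with an optional zero-force flight window around peak bar
#' height.
#'
#' @param y_max_cm,y_catch_cm Peak and catch bar height above start (cm).
#' @param x1_cm,x2_cm,x3_cm Programmed AP displacements (cm, positive toward
#'   the lifter). Requires `x2_cm < min(x1_cm, x3_cm)`.
#' @param v_max Peak vertical bar velocity (m/s).
#' @param duration Movement duration start to catch (s). Must leave room for
#'   the rise (`y_max/v_max` plus one ramp) and an unhurried descent.
#' @param body_mass,body_height,barbell_mass Subject and bar (kg, m, kg).
#' @param flight Simulate a flight phase (zero-force window).
#' @param flight_lead Flight onset before peak bar height (s).
#' @param flight_duration Total unweighted window (s), including tapers.
#' @param taper Half-cosine force ramp length at the flight edges (s).
#' @param com_coupling,catch_coupling Fraction of bar acceleration passed to
#'   the surrogate system acceleration during pull / after peak height.
#' @param dip_cm Depth of the away-drift below X1 at the end of the first
#'   pull (cm); guarantees X1 is a true turning point.
#' @param noise_sd_pos_mm Marker noise SD (mm, per axis).
#' @param noise_sd_force_n Force noise SD (N, per plate component).
#' @param marker_asym_mm Amplitude of the left/right marker wobble that the
#'   centre computation must cancel (mm).
#' @param bar_half_width ML distance of each marker from the bar centre (m).
#' @param pre_quiet,post_hold Quiet standing before start / hold after catch
#'   (s).
#' @param f_kin,f_force Sampling rates (Hz).
#' @param seed Optional integer; makes the trial reproducible.
#'
#' @return Object of class `trial_params`.
#' @export
trial_params <- function(y_max_cm = 161, y_catch_cm = 141,
                         x1_cm = 0.3, x2_cm = -16.5, x3_cm = 9,
                         v_max = 3.15, duration = 1.30,
                         body_mass = 75, body_height = 1.78,
                         barbell_mass = 20,
                         flight = TRUE, flight_lead = 0.05,
                         flight_duration = 0.20, taper = 0.08,
                         com_coupling = 0.85, catch_coupling = 0.2,
                         dip_cm = 2,
                         noise_sd_pos_mm = 0.5, noise_sd_force_n = 5,
                         marker_asym_mm = 2, bar_half_width = 0.6,
                         pre_quiet = 1.0, post_hold = 0.5,
                         f_kin = 250, f_force = 1000, seed = NULL) {
  if (duration <= 0.5) stop("trial_params: duration must exceed 0.5 s")
  if (y_max_cm <= y_catch_cm + 0.1)
    stop("trial_params: y_max_cm must exceed y_catch_cm")
  if (x2_cm >= min(x1_cm - dip_cm, x3_cm))
    stop("trial_params: x2_cm must be below x3_cm and below x1_cm - dip_cm ",
         "(the turnover is the most-away point of the path)")
  if (noise_sd_pos_mm < 0 || noise_sd_force_n < 0)
    stop("trial_params: noise SDs must be >= 0")
  t_up <- .rise_time(y_max_cm / 100, v_max)
  t_down_min <- max(0.25, 2 * ((y_max_cm - y_catch_cm) / 100) / (0.9 * v_max))
  if (duration < t_up + t_down_min)
    stop(sprintf(paste0(
      "trial_params: duration %.2f s too short for y_max %.0f cm at v_max ",
      "%.2f m/s; need at least %.2f s"), duration, y_max_cm, v_max,
      t_up + t_down_min))
  if (flight) {
    if (flight_duration <= 2 * taper + 0.02)
      stop("trial_params: inconsistent flight window (shorter than its tapers)")
    if (flight_lead >= t_up || flight_duration - flight_lead >= duration - t_up)
      stop("trial_params: inconsistent flight window (outside the movement)")
  }
  structure(list(y_max_cm = y_max_cm, y_catch_cm = y_catch_cm,
                 x1_cm = x1_cm, x2_cm = x2_cm, x3_cm = x3_cm,
                 v_max = v_max, duration = duration,
                 body_mass = body_mass, body_height = body_height,
                 barbell_mass = barbell_mass,
                 flight = flight, flight_lead = flight_lead,
                 flight_duration = flight_duration, taper = taper,
                 com_coupling = com_coupling, catch_coupling = catch_coupling,
                 dip_cm = dip_cm,
                 noise_sd_pos_mm = noise_sd_pos_mm,
                 noise_sd_force_n = noise_sd_force_n,
                 marker_asym_mm = marker_asym_mm,
                 bar_half_width = bar_half_width,
                 pre_quiet = pre_quiet, post_hold = post_hold,
                 f_kin = f_kin, f_force = f_force, seed = seed),
            class = "trial_params")
}

# quintic smoothstep and its integral / derivative (zero first and second
# derivative at both ends, so piecewise paths are C2 and spectrally gentle
# under the 4 Hz zero-phase filter)
.sstep <- function(u) u^3 * (10 - 15 * u + 6 * u^2)
.sstep_int <- function(u) u^4 * (2.5 - 3 * u + u^2)
.sstep_d <- function(u) 30 * u^2 * (1 - u)^2

# rise duration of the ramp-plateau-ramp velocity profile: the bar reaches
# peak velocity v_max with smoothstep ramps of length ta and holds it so the
# climb integrates exactly to y_max
.rise_ramp <- function(ym, vmax) min(0.40, ym / vmax)
.rise_time <- function(ym, vmax) ym / vmax + .rise_ramp(ym, vmax)

# closed-form vertical position/velocity/acceleration: smoothstep
# ramp-plateau-ramp velocity up to y_max, then a sin^2 velocity pulse down to
# y_catch
.vert_profile <- function(p) {
  ym <- p$y_max_cm / 100; yc <- p$y_catch_cm / 100
  vm <- p$v_max
  ta <- .rise_ramp(ym, vm)
  t_up <- .rise_time(ym, vm)
  tp <- t_up - 2 * ta
  t_down <- p$duration - t_up
  v_down <- 2 * (ym - yc) / t_down
  t0 <- p$pre_quiet
  t1 <- t0 + t_up
  t2 <- t0 + p$duration
  rise_pos <- function(tau) {
    y <- numeric(length(tau))
    i1 <- tau <= ta
    y[i1] <- vm * ta * .sstep_int(tau[i1] / ta)
    i2 <- tau > ta & tau <= ta + tp
    y[i2] <- vm * ta / 2 + vm * (tau[i2] - ta)
    i3 <- tau > ta + tp
    u <- (tau[i3] - ta - tp) / ta
    y[i3] <- vm * ta / 2 + vm * tp + vm * ta * (u - .sstep_int(u))
    y
  }
  rise_acc <- function(tau) {
    a <- numeric(length(tau))
    i1 <- tau <= ta
    a[i1] <- vm * .sstep_d(tau[i1] / ta) / ta
    i3 <- tau > ta + tp
    a[i3] <- -vm * .sstep_d((tau[i3] - ta - tp) / ta) / ta
    a
  }
  pos <- function(t) {
    y <- numeric(length(t))
    ri <- t > t0 & t <= t1
    y[ri] <- rise_pos(t[ri] - t0)
    di <- t > t1 & t <= t2
    s <- t[di] - t1
    y[di] <- ym - v_down * (s / 2 - t_down / (4 * pi) * sin(2 * pi * s / t_down))
    y[t > t2] <- yc
    y
  }
  acc <- function(t) {
    a <- numeric(length(t))
    ri <- t > t0 & t <= t1
    a[ri] <- rise_acc(t[ri] - t0)
    di <- t > t1 & t <= t2
    a[di] <- -v_down * pi / t_down * sin(2 * pi * (t[di] - t1) / t_down)
    a
  }
  list(pos = pos, acc = acc, t_start = t0, t_ymax = t1, t_catch = t2,
       t_up = t_up, t_down = t_down, v_down = v_down)
}

# C2 piecewise-smoothstep AP path through the labelled control points; every
# knot is a stationary point, so the programmed extremes are exact
.ap_profile <- function(p, vp) {
  t_end <- vp$t_catch + p$post_hold
  t_pre <- vp$t_start + 0.18 * vp$t_up
  t_x1 <- vp$t_start + 0.40 * vp$t_up
  t_x2 <- vp$t_ymax - 0.10 * vp$t_down   # most-away point just before peak height
  kt <- c(0, vp$t_start, t_pre, t_x1, t_x2, vp$t_catch, t_end)
  kx <- c(0, 0, (p$x1_cm - p$dip_cm) / 100, p$x1_cm / 100, p$x2_cm / 100,
          p$x3_cm / 100, p$x3_cm / 100)
  function(t) {
    i <- findInterval(t, kt, rightmost.closed = TRUE)
    i[i < 1] <- 1L
    i[i >= length(kt)] <- length(kt) - 1L
    u <- (t - kt[i]) / (kt[i + 1] - kt[i])
    u <- pmin(1, pmax(0, u))
    kx[i] + (kx[i + 1] - kx[i]) * .sstep(u)
  }
}

# flight weighting: 1 outside the window, 0 on the plateau, half-cosine tapers
.flight_weight <- function(t, t_fo, dur, taper) {
  w <- rep(1, length(t))
  t_land <- t_fo + dur
  ramp_in <- t >= t_fo & t < t_fo + taper
  w[ramp_in] <- (1 + cos(pi * (t[ramp_in] - t_fo) / taper)) / 2
  w[t >= t_fo + taper & t <= t_land - taper] <- 0
  ramp_out <- t > t_land - taper & t <= t_land
  w[ramp_out] <- (1 - cos(pi * (t[ramp_out] - (t_land - taper)) / taper)) / 2
  w
}

#' Generate a synthetic snatch trial
#'
#' Builds the marker and force-plate time series described by a
#' [trial_params] object, together with the ground-truth feature values the
#' processing pipeline should recover. Deterministic for a fixed
#' `p$seed`.
#'
#' @param p A [trial_params].
#' @param subject_id,condition,trial_index Identity stamped on the trial.
#'
#' @return List of class `snatch_sim` with `raw` (a [raw_trial]), `truth`
#'   (list: `x1_cm`, `x2_cm`, `x3_cm`, `y_max_cm`, `y_catch_cm`, `v_max`,
#'   `duration`, `t_start`, `t_ymax`, `t_catch`, `takeoff_time` (NA without
#'   flight), `vgrf_max_bw`, `body_weight_n`) and `params`.
#' @export
generate_trial <- function(p = trial_params(), subject_id = "S01",
                           condition = "DL", trial_index = 1) {
  stopifnot(inherits(p, "trial_params"))
  if (!is.null(p$seed)) set.seed(p$seed)
  vp <- .vert_profile(p)
  apf <- .ap_profile(p, vp)
  t_end <- vp$t_catch + p$post_hold

  tk <- seq(0, t_end, by = 1 / p$f_kin)
  pos_v <- vp$pos(tk)
  pos_ap <- apf(tk)
  asym <- p$marker_asym_mm / 1000
  d_ap <- asym * sin(2 * pi * 1.1 * tk)
  d_v <- asym * sin(2 * pi * 0.9 * tk + 1)
  noise <- function(n) stats::rnorm(n, 0, p$noise_sd_pos_mm / 1000)
  nk <- length(tk)
  marker_left <- cbind(AP = pos_ap + d_ap + noise(nk),
                       ML = rep(p$bar_half_width, nk) + noise(nk),
                       V = pos_v + d_v + noise(nk))
  marker_right <- cbind(AP = pos_ap - d_ap + noise(nk),
                        ML = rep(-p$bar_half_width, nk) + noise(nk),
                        V = pos_v - d_v + noise(nk))

  tf <- seq(0, t_end, by = 1 / p$f_force)
  g <- 9.81
  m_tot <- p$body_mass + p$barbell_mass
  a_bar <- vp$acc(tf)
  coup <- ifelse(tf <= vp$t_ymax, p$com_coupling, p$catch_coupling)
  # surrogate system acceleration: coupled bar acceleration, floored at -0.7 g
  # (a grounded lifter cannot unweight much further without leaving the plates)
  a_sur <- pmax(coup * a_bar, -0.7 * g)
  force <- pmax(0, m_tot * (g + a_sur))
  takeoff_time <- NA_real_
  if (p$flight) {
    t_fo <- vp$t_ymax - p$flight_lead
    force <- force * .flight_weight(tf, t_fo, p$flight_duration, p$taper)
  }
  bw <- p$body_mass * g
  if (p$flight) {
    thr_idx <- which(tf > vp$t_start & force < 0.05 * bw)
    takeoff_time <- tf[thr_idx[1]]
  }
  move <- tf >= vp$t_start & tf <= vp$t_catch
  vgrf_max_bw <- max(force[move]) / bw

  split <- 0.5 + 0.05 * sin(2 * pi * 0.4 * tf)
  nf <- length(tf)
  fnoise <- function(n) stats::rnorm(n, 0, p$noise_sd_force_n)
  plate1 <- cbind(AP = fnoise(nf), ML = fnoise(nf),
                  V = split * force + fnoise(nf))
  plate2 <- cbind(AP = fnoise(nf), ML = fnoise(nf),
                  V = (1 - split) * force + fnoise(nf))

  raw <- raw_trial(subject_id, condition, trial_index,
                   marker_left, marker_right, p$f_kin,
                   plate1, plate2, p$f_force)
  truth <- list(x1_cm = p$x1_cm, x2_cm = p$x2_cm, x3_cm = p$x3_cm,
                y_max_cm = p$y_max_cm, y_catch_cm = p$y_catch_cm,
                v_max = p$v_max, duration = p$duration,
                t_start = vp$t_start, t_ymax = vp$t_ymax,
                t_catch = vp$t_catch, takeoff_time = takeoff_time,
                vgrf_max_bw = vgrf_max_bw, body_weight_n = bw)
  structure(list(raw = raw, truth = truth, params = p), class = "snatch_sim")
}

#' Generate a static (no-barbell) record
#'
#' Constant body-weight vertical force split between the two plates, with
#' Gaussian sensor noise.
#'
#' @param body_mass Subject mass (kg).
#' @param subject_id Identifier.
#' @param duration Record length (s).
#' @param split Fraction of the weight on plate 1.
#' @param noise_sd_force_n Noise SD per component (N).
#' @param f_force Sampling rate (Hz).
#' @param gravity Gravitational acceleration (m/s^2).
#' @param seed Optional integer seed.
#'
#' @return A [static_record].
#' @export
generate_static <- function(body_mass = 75, subject_id = "S01", duration = 2,
                            split = 0.55, noise_sd_force_n = 5,
                            f_force = 1000, gravity = 9.81, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration * f_force))
  w <- body_mass * gravity
  fn <- function() stats::rnorm(n, 0, noise_sd_force_n)
  plate1 <- cbind(AP = fn(), ML = fn(), V = split * w + fn())
  plate2 <- cbind(AP = fn(), ML = fn(), V = (1 - split) * w + fn())
  static_record(subject_id, plate1, plate2, f_force)
}

#' Cohort simulation parameters
#'
#' Hierarchical model for a subjects x conditions x trials cohort: each
#' varying trial parameter is drawn as
#' `mu + condition_shift + subject_effect + trial_noise`, with the subject
#' effect variance a fraction `icc` of the total between-subject variance of
#' condition means and the trial noise scaled so that subject-by-condition
#' means keep that total variance. With all shifts zero (the default) the
#' cohort is a global null: no condition changes any parameter, matching a
#' study design whose learning conditions produced no systematic
#' biomechanical differences.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials Trials per subject and condition.
#' @param icc Correlation between a subject's condition means, in [0, 1).
#' @param means,sds Named numeric vectors overriding the default population
#'   means / between-subject SDs of the varying parameters (`y_max_cm`,
#'   `vtr_cm`, `x1_cm`, `x2_cm`, `x3_cm`, `v_max`, `duration`).
#' @param shifts Named list of per-condition mean shifts, e.g.
#'   `list(x1_cm = c(DL = 2))`; conditions not named shift by 0.
#' @param noise_sd_pos_mm,noise_sd_force_n Sensor noise passed to each trial.
#' @param seed Optional integer seed.
#'
#' @return Object of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 16, n_trials = 3, icc = 0.5,
                          means = NULL, sds = NULL, shifts = NULL,
                          noise_sd_pos_mm = 0.5, noise_sd_force_n = 5,
                          seed = NULL) {
  if (icc < 0 || icc >= 1) stop("cohort_params: icc must lie in [0, 1)")
  mu <- c(y_max_cm = 161, vtr_cm = 18.4, x1_cm = -0.3, x2_cm = -16.5,
          x3_cm = 9, v_max = 3.16, duration = 1.30)
  sd0 <- c(y_max_cm = 17, vtr_cm = 12, x1_cm = 7, x2_cm = 7,
           x3_cm = 9.5, v_max = 0.44, duration = 0.24)
  if (!is.null(means)) mu[names(means)] <- means
  if (!is.null(sds)) sd0[names(sds)] <- sds
  if (any(sd0 < 0)) stop("cohort_params: sds must be >= 0")
  shifts <- shifts %||% list()
  structure(list(n_subjects = n_subjects, n_trials = n_trials, icc = icc,
                 means = mu, sds = sd0, shifts = shifts,
                 noise_sd_pos_mm = noise_sd_pos_mm,
                 noise_sd_force_n = noise_sd_force_n, seed = seed),
            class = "cohort_params")
}

# draw one variable for the whole cohort grid
.draw_var <- function(grid, mu, sdv, icc, n_trials, shift) {
  subjects <- unique(grid$subject_id)
  b <- stats::rnorm(length(subjects), 0, sqrt(icc) * sdv)
  names(b) <- subjects
  e <- stats::rnorm(nrow(grid), 0, sqrt(n_trials * (1 - icc)) * sdv)
  sh <- rep(0, nrow(grid))
  if (!is.null(shift)) {
    for (cond in names(shift))
      sh[grid$condition == cond] <- shift[[cond]]
  }
  mu + sh + b[grid$subject_id] + e
}

#' Generate a synthetic cohort
#'
#' Draws per-trial ground-truth parameters for `n_subjects` x 4 conditions x
#' `n_trials` trials from the hierarchical model of [cohort_params], applies
#' the feasibility constraints of [trial_params] (descent below peak
#' velocity, turnover below pull and catch, positive travel range), and
#' optionally synthesises and writes every trial's marker/force files plus a
#' static record per subject and a YAML manifest.
#'
#' @param cp A [cohort_params].
#' @param dir Output directory; when `NULL` (default) only the ground-truth
#'   table is produced, which is sufficient for statistical calibration work.
#'
#' @return Object of class `snatch_cohort`: list with `subjects`, `truth`
#'   (one row per trial: identity columns plus `Y_max`, `Y_catch`, `VTR`,
#'   `X1`, `X2`, `X3_DxT`, `V_max`, `MvT_duration` ground-truth values),
#'   `manifest` (path or `NULL`) and `params`.
#' @export
generate_cohort <- function(cp = cohort_params(), dir = NULL) {
  stopifnot(inherits(cp, "cohort_params"))
  if (!is.null(cp$seed)) set.seed(cp$seed)
  ids <- sprintf("S%02d", seq_len(cp$n_subjects))
  subjects <- data.frame(subject_id = ids,
                         body_height = pmin(2.1, pmax(1.55,
                           stats::rnorm(cp$n_subjects, 1.78, 0.06))),
                         body_mass = pmin(130, pmax(50,
                           stats::rnorm(cp$n_subjects, 75, 8))),
                         stringsAsFactors = FALSE)
  grid <- expand.grid(trial_index = seq_len(cp$n_trials),
                      condition = snatch_conditions(), subject_id = ids,
                      stringsAsFactors = FALSE)[, c("subject_id", "condition",
                                                    "trial_index")]
  draw <- function(v) .draw_var(grid, cp$means[[v]], cp$sds[[v]], cp$icc,
                                cp$n_trials, cp$shifts[[v]])
  y_max <- pmax(draw("y_max_cm"), 120)
  # feasibility floors: a real drop-under is at least a few centimetres and
  # takes at least ~0.3 s; the turnover must be the deepest away excursion
  vtr <- pmax(5, draw("vtr_cm"))
  x1 <- draw("x1_cm")
  x3 <- draw("x3_cm")
  x2 <- pmin(draw("x2_cm"), pmin(x1 - 2, x3) - 1)
  v_max <- pmin(pmax(2.2, draw("v_max")), 2.5 * y_max / 100)
  # descent at most ~1.5 m/s peak and the forward loop into the catch at
  # most ~1.1 m/s peak: a real drop-under is unhurried relative to the pull
  dur_min <- .rise_time(y_max / 100, v_max) +
    pmax(0.30, 2 * (vtr / 100) / 1.5, 1.55 * (x3 - x2) / 100)
  duration <- pmax(draw("duration"), dur_min + 0.05)
  truth <- cbind(grid,
                 data.frame(Y_max = y_max, Y_catch = y_max - vtr, VTR = vtr,
                            X1 = x1, X2 = x2, X3_DxT = x3, V_max = v_max,
                            MvT_duration = duration))
  manifest_path <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    trial_seeds <- sample.int(.Machine$integer.max, nrow(grid) + cp$n_subjects)
    subj_entries <- list()
    for (i in seq_len(cp$n_subjects)) {
      sfile <- sprintf("%s_static.tsv", ids[i])
      st <- generate_static(subjects$body_mass[i], ids[i],
                            noise_sd_force_n = cp$noise_sd_force_n,
                            seed = trial_seeds[nrow(grid) + i])
      write_force_file(st$plate1, st$plate2, st$f_force, file.path(dir, sfile))
      subj_entries[[i]] <- list(id = ids[i],
                                body_height = subjects$body_height[i],
                                static_file = sfile)
    }
    trial_entries <- list()
    for (i in seq_len(nrow(grid))) {
      row <- truth[i, ]
      p <- .params_from_truth(row, subjects, cp, seed = trial_seeds[i])
      sim <- generate_trial(p, row$subject_id, row$condition, row$trial_index)
      stem <- sprintf("%s_%s_%d", row$subject_id, row$condition,
                      row$trial_index)
      write_trial(sim$raw, file.path(dir, paste0(stem, "_markers.tsv")),
                  file.path(dir, paste0(stem, "_force.tsv")))
      trial_entries[[i]] <- list(subject = row$subject_id,
                                 condition = row$condition,
                                 trial = row$trial_index,
                                 marker_file = paste0(stem, "_markers.tsv"),
                                 force_file = paste0(stem, "_force.tsv"))
    }
    manifest_path <- file.path(dir, "manifest.yaml")
    yaml::write_yaml(list(subjects = subj_entries, trials = trial_entries),
                     manifest_path)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  structure(list(subjects = subjects, truth = truth,
                 manifest = manifest_path, params = cp),
            class = "snatch_cohort")
}

# trial parameters for one ground-truth row of a cohort
.params_from_truth <- function(row, subjects, cp, seed = NULL,
                               noise_sd_pos_mm = cp$noise_sd_pos_mm,
                               noise_sd_force_n = cp$noise_sd_force_n) {
  si <- match(row$subject_id, subjects$subject_id)
  t_down <- row$MvT_duration - .rise_time(row$Y_max / 100, row$V_max)
  trial_params(y_max_cm = row$Y_max, y_catch_cm = row$Y_catch,
               x1_cm = row$X1, x2_cm = row$X2, x3_cm = row$X3_DxT,
               v_max = row$V_max, duration = row$MvT_duration,
               flight = t_down >= 0.25,
               body_mass = subjects$body_mass[si],
               body_height = subjects$body_height[si],
               noise_sd_pos_mm = noise_sd_pos_mm,
               noise_sd_force_n = noise_sd_force_n,
               seed = seed)
}

#' Trial parameters for one trial of a generated cohort
#'
#' Rebuilds the [trial_params] of row `i` of a cohort's ground-truth table,
#' optionally overriding the sensor noise (e.g. `noise_sd_pos_mm = 0` for
#' noiseless parameter-recovery checks).
#'
#' @param cohort A [generate_cohort] result.
#' @param i Row of `cohort$truth`.
#' @param noise_sd_pos_mm,noise_sd_force_n Sensor noise overrides.
#' @param seed Optional seed for the trial.
#'
#' @return A [trial_params].
#' @export
cohort_trial_params <- function(cohort, i,
                                noise_sd_pos_mm = cohort$params$noise_sd_pos_mm,
                                noise_sd_force_n = cohort$params$noise_sd_force_n,
                                seed = NULL) {
  .params_from_truth(cohort$truth[i, ], cohort$subjects, cohort$params,
                     seed = seed, noise_sd_pos_mm = noise_sd_pos_mm,
                     noise_sd_force_n = noise_sd_force_n)
}

#' @export
print.snatch_cohort <- function(x, ...) {
  cat(sprintf("snatch_cohort: %d subjects x 4 conditions x %d trials (%d rows)%s\n",
              x$params$n_subjects, x$params$n_trials, nrow(x$truth),
              if (is.null(x$manifest)) " [truth only]" else
                paste0("; files under ", dirname(x$manifest))))
  invisible(x)
}
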