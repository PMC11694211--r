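#' Barbell centre from the two bar-end markers
#'
#' Per-sample arithmetic mean of the left and right bar-end markers, so that
#' symmetric marker placement errors and asymmetric bar wobble cancel. Only
#' the anteroposterior and vertical components are retained.
#'
#' @param marker_left,marker_right n x 3 matrices (AP, ML, V), metres.
#'
#' @return n x 2 matrix with columns AP, V (metres).
#' @export
barbell_center <- function(marker_left, marker_right) {
  if (nrow(marker_left) != nrow(marker_right))
    stop("barbell_center: marker series must have equal length")
  ctr <- (marker_left + marker_right) / 2
  ctr[, c("AP", "V"), drop = FALSE]
}

#' Body weight from a static record
#'
#' Mean of the summed vertical plate forces over the quiet-standing record.
#'
#' @param static A [static_record].
#' @param gravity Gravitational acceleration used for the mass conversion.
#'
#' @return List with `weight_n` (N) and `mass_kg`.
#' @export
body_weight_from_static <- function(static, gravity = 9.81) {
  stopifnot(inherits(static, "static_record"))
  w <- mean(static$plate1[, "V"] + static$plate2[, "V"])
  if (!is.finite(w) || w <= 0)
    stop("body_weight_from_static: non-positive mean vertical force; ",
         "check frame/sign convention")
  list(weight_n = w, mass_kg = w / gravity)
}

#' Total ground reaction force from two plates
#'
#' Per-sample vector sum of both force plates.
#'
#' @param plate1,plate2 m x 3 force matrices (AP, ML, V), newtons.
#'
#' @return List with `total` (m x 3 matrix) and `vertical` (numeric vector).
#' @export
total_grf <- function(plate1, plate2) {
  if (nrow(plate1) != nrow(plate2))
    stop("total_grf: plate series must have equal length")
  tot <- plate1 + plate2
  list(total = tot, vertical = tot[, "V"])
}

#' Rate of force development series
#'
#' Difference of consecutive vGRF readings divided by the sampling interval:
#' `rfd[i] = (vgrf[i+1] - vgrf[i]) / dt`. The last sample repeats the
#' penultimate one so the series keeps the input length.
#'
#' @param vgrf vGRF series (any unit; BW gives RFD in BW/s).
#' @param dt Sampling interval (s), 0.001 for a 1000 Hz plate.
#'
#' @return Numeric series, same length as `vgrf`.
#' @export
rfd_series <- function(vgrf, dt = 0.001) {
  n <- length(vgrf)
  if (n < 2) stop("rfd_series: need at least 2 samples")
  out <- c(diff(vgrf) / dt, 0)
  out[n] <- out[n - 1]
  out
}

#' Preprocess a raw trial into analysis-ready signals
#'
#' Full preprocessing chain: low-pass filter the barbell centre (4 Hz default)
#' and the summed vertical GRF (15 Hz default), subtract the initial barbell
#' position so every trajectory starts at (0, 0), differentiate position twice
#' for velocity and acceleration, express vGRF in body-weight multiples,
#' derive the rate of force development (per force-plate sampling interval)
#' and the mass-normalised power (vGRF in BW x g x vertical barbell velocity,
#' W/kg, with velocity linearly interpolated onto the force timebase), detect
#' the phase events, and compute 101-point time-normalised curves of the
#' start-to-catch phase (positions and velocity normalised by body height,
#' vGRF by body mass).
#'
#' Discrete features are always extracted from the native-rate signals; the
#' time-normalised curves are for export and visualisation only, so peak
#' values are not distorted by resampling.
#'
#' @param raw A [raw_trial].
#' @param subject A [subject_info].
#' @param cfg A [pipeline_config].
#'
#' @return Object of class `trial_signals` with elements `pos` (n x 2, m),
#'   `vel`, `acc`, `f_kin`, `vgrf_n`, `vgrf_bw`, `rfd_bw`, `power_wkg`,
#'   `vel_force` (velocity on the force timebase), `f_force`,
#'   `body_weight_n`, `body_mass`, `body_height`, `events` (a
#'   [phase_events] object) and `norm_curves`.
#' @export
normalize_trial <- function(raw, subject, cfg = pipeline_config()) {
  stopifnot(inherits(raw, "raw_trial"), inherits(subject, "subject_info"))
  ctr <- barbell_center(raw$marker_left, raw$marker_right)
  pos <- apply(ctr, 2, butter_lowpass, fs = raw$f_kin,
               cutoff = cfg$cutoff_kin, order = cfg$filter_order)
  colnames(pos) <- c("AP", "V")
  pos <- sweep(pos, 2, pos[1, ])     # baseline: first filtered sample
  vel <- apply(pos, 2, differentiate, fs = raw$f_kin)
  acc <- apply(vel, 2, differentiate, fs = raw$f_kin)

  bw <- subject$body_mass * cfg$gravity
  grf_v <- total_grf(raw$plate1, raw$plate2)$vertical
  vgrf_n <- butter_lowpass(grf_v, fs = raw$f_force,
                           cutoff = cfg$cutoff_force, order = cfg$filter_order)
  vgrf_bw <- vgrf_n / bw
  nf <- length(vgrf_bw)
  rfd_bw <- rfd_series(vgrf_bw, cfg$rfd_interval)
  t_kin <- (seq_len(nrow(pos)) - 1) / raw$f_kin
  t_force <- (seq_len(nf) - 1) / raw$f_force
  vel_force <- stats::approx(t_kin, vel[, "V"], xout = t_force, rule = 2)$y
  power_wkg <- vgrf_bw * cfg$gravity * vel_force

  events <- segment_phases(pos, vel, vgrf_bw,
                           f_kin = raw$f_kin, f_force = raw$f_force, cfg = cfg)

  nc <- NULL
  if (!is.null(events)) {
    tn <- function(x) time_normalize(x, events$start_idx, events$catch_idx,
                                     cfg$n_time_points)
    h <- subject$body_height
    f_of_k <- function(i) 1 + round((i - 1) / raw$f_kin * raw$f_force)
    # trimmed position curves are re-zeroed at the movement start so every
    # exported trajectory begins at exactly 0
    nc <- list(
      pos_ap = (tn(pos[, "AP"]) - pos[events$start_idx, "AP"]) / h,
      pos_v  = (tn(pos[, "V"]) - pos[events$start_idx, "V"]) / h,
      vel_v  = tn(vel[, "V"]) / h,
      vgrf_n_per_kg = time_normalize(vgrf_n, f_of_k(events$start_idx),
                                     min(nf, f_of_k(events$catch_idx)),
                                     cfg$n_time_points) / subject$body_mass)
  }

  structure(list(pos = pos, vel = vel, acc = acc, f_kin = raw$f_kin,
                 vgrf_n = vgrf_n, vgrf_bw = vgrf_bw, rfd_bw = rfd_bw,
                 power_wkg = power_wkg, vel_force = vel_force,
                 f_force = raw$f_force,
                 body_weight_n = bw, body_mass = subject$body_mass,
                 body_height = subject$body_height,
                 events = events, norm_curves = nc, cfg = cfg),
            class = "trial_signals")
}

#' @export
print.trial_signals <- function(x, ...) {
  cat(sprintf("trial_signals: %d kin samples @ %g Hz, %d force samples @ %g Hz\n",
              nrow(x$pos), x$f_kin, length(x$vgrf_bw), x$f_force))
  if (!is.null(x$events)) print(x$events)
  invisible(x)
}
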