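#' Derived displacement parameters
#'
#' Arithmetic identities linking the primary bar-path parameters to the
#' derived ones: the vertical travel range VTR = Y_max - Y_catch (the drop
#' under the bar), the pull-phase horizontal range DxV = X1 - X2, the loop
#' DxL = X3 - X2 (most forward point to catch) and the total net displacement
#' DxT = X3. All values in centimetres.
#'
#' @param y_max,y_catch Peak and catch bar height (cm).
#' @param x1,x2,x3 Net AP displacements at pull extreme, turnover extreme and
#'   catch (cm, positive toward the lifter).
#'
#' @return List with `VTR`, `DxV`, `DxL`, `DxT` (cm).
#' @export
#' @examples
#' snatch_derived(161.44, 140.75, 0.31, -16.93, 9.19)$VTR  # 20.69
snatch_derived <- function(y_max, y_catch, x1, x2, x3) {
  list(VTR = y_max - y_catch, DxV = x1 - x2, DxL = x3 - x2, DxT = x3)
}

#' Kinematic feature set of one trial
#'
#' Discrete kinematic parameters over the start-to-catch phase, computed on
#' the native-rate signals: movement duration, average and peak vertical
#' velocity, peak vertical acceleration, peak and catch bar height, and the
#' anteroposterior displacement family X1/X2/X3 with its derived ranges.
#'
#' @param signals A [normalize_trial] result.
#' @param events A [phase_events] object (defaults to the events stored in
#'   `signals`).
#'
#' @return Named list: `MvT_duration` (s), `V_avg`, `V_max` (m/s), `Acc_max`
#'   (m/s^2), `Y_max`, `Y_catch`, `VTR`, `X1`, `X2`, `X3_DxT`, `DxL`, `DxV`
#'   (cm).
#' @export
kinematic_features <- function(signals, events = signals$events) {
  s <- events$start_idx; ct <- events$catch_idx
  win <- s:ct
  vpos <- signals$pos[, "V"]; vvel <- signals$vel[, "V"]
  if (is.na(events$rearmost_idx) || is.na(events$foremost_idx)) {
    hx <- horizontal_extremes(signals$pos[, "AP"], events)
  } else {
    hx <- list(x1_cm = 100 * signals$pos[events$rearmost_idx, "AP"],
               x2_cm = 100 * signals$pos[events$foremost_idx, "AP"],
               x3_cm = 100 * signals$pos[ct, "AP"])
  }
  y_max <- 100 * vpos[events$ymax_idx]
  y_catch <- 100 * vpos[ct]
  der <- snatch_derived(y_max, y_catch, hx$x1_cm, hx$x2_cm, hx$x3_cm)
  list(MvT_duration = (ct - s) / signals$f_kin,
       V_avg = mean(vvel[win]),
       V_max = max(vvel[win]),
       Acc_max = max(signals$acc[win, "V"]),
       Y_max = y_max, Y_catch = y_catch, VTR = der$VTR,
       X1 = hx$x1_cm, X2 = hx$x2_cm, X3_DxT = der$DxT,
       DxL = der$DxL, DxV = der$DxV)
}

#' Kinetic feature set of one trial
#'
#' Discrete kinetic parameters from the body-weight normalised vGRF: peak and
#' mean vGRF (BW), peak and mean rate of force development (BW/s, successive
#' 1 ms force-plate readings) and peak and mean mass-normalised power (W/kg,
#' vGRF in BW x g x vertical barbell velocity interpolated onto the force
#' timebase). "all" variants cover start to catch; "jump" variants cover
#' start to takeoff. When no flight is detected the jump variants fall back
#' to the whole movement and `jump_detected` is `FALSE`.
#'
#' @inheritParams kinematic_features
#'
#' @return Named list: `vGRF_max`, `vGRF_mean_all`, `vGRF_mean_jump` (BW),
#'   `RFD_max_all`, `RFD_max_jump`, `RFD_mean_all`, `RFD_mean_jump` (BW/s),
#'   `Power_max_all`, `Power_max_jump`, `Power_mean_all`, `Power_mean_jump`
#'   (W/kg), `jump_detected`.
#' @export
kinetic_features <- function(signals, events = signals$events) {
  f_of_k <- function(i) 1L + as.integer(round((i - 1) / signals$f_kin * signals$f_force))
  nf <- length(signals$vgrf_bw)
  fs <- min(nf, f_of_k(events$start_idx))
  fc <- min(nf, f_of_k(events$catch_idx))
  jump_detected <- !is.na(events$takeoff_idx) && events$takeoff_idx > fs
  fj <- if (jump_detected) min(events$takeoff_idx, fc) else fc
  all_w <- fs:fc
  jump_w <- fs:fj
  v <- signals$vgrf_bw; r <- signals$rfd_bw; p <- signals$power_wkg
  list(vGRF_max = max(v[all_w]),
       vGRF_mean_all = mean(v[all_w]),
       vGRF_mean_jump = mean(v[jump_w]),
       RFD_max_all = max(r[all_w]), RFD_max_jump = max(r[jump_w]),
       RFD_mean_all = mean(r[all_w]), RFD_mean_jump = mean(r[jump_w]),
       Power_max_all = max(p[all_w]), Power_max_jump = max(p[jump_w]),
       Power_mean_all = mean(p[all_w]), Power_mean_jump = mean(p[jump_w]),
       jump_detected = jump_detected)
}

#' Classify a barbell path against the optimal pattern
#'
#' The optimal snatch bar path moves toward the lifter during the pull,
#' away during the turnover, and back toward the lifter into the catch:
#' a strictly positive-negative-positive (X1, X2, X3) sign pattern in the
#' canonical frame. Zero counts as neither positive nor negative, so a flat
#' component is never optimal.
#'
#' @param x1,x2,x3 Net AP displacements (cm).
#'
#' @return List with `sign_pattern` (character triple from "+", "-", "0")
#'   and `is_optimal`.
#' @export
#' @examples
#' classify_path(0.31, -16.93, 9.19)$is_optimal   # TRUE
#' classify_path(-0.88, -16.32, 10.5)$is_optimal  # FALSE (X1 negative)
classify_path <- function(x1, x2, x3) {
  sgn <- function(v) if (v > 0) "+" else if (v < 0) "-" else "0"
  list(sign_pattern = c(X1 = sgn(x1), X2 = sgn(x2), X3 = sgn(x3)),
       is_optimal = (x1 > 0) && (x2 < 0) && (x3 > 0))
}

#' Per-subject adherence to the optimal path
#'
#' A subject adheres to the optimal trajectory under a condition only if
#' every one of their repetitions classifies as optimal.
#'
#' @param is_optimal Logical vector, one element per trial of one subject
#'   under one condition.
#'
#' @return Single logical.
#' @export
subject_adherence <- function(is_optimal) {
  if (length(is_optimal) < 1)
    stop("subject_adherence: need at least one trial")
  all(as.logical(is_optimal))
}

#' Process a raw trial end to end
#'
#' Preprocessing, phase segmentation, feature extraction and path
#' classification for a single trial.
#'
#' @param raw A [raw_trial].
#' @param subject A [subject_info].
#' @param cfg A [pipeline_config].
#'
#' @return Object of class `snatch_trial` with elements `signals`, `events`,
#'   `features` (one-row data frame, see [features_row]) and
#'   `classification`.
#' @export
process_trial <- function(raw, subject, cfg = pipeline_config()) {
  signals <- normalize_trial(raw, subject, cfg)
  events <- signals$events
  kin <- kinematic_features(signals, events)
  kin_kinetic <- kinetic_features(signals, events)
  cls <- classify_path(kin$X1, kin$X2, kin$X3)
  feat <- features_row(raw$subject_id, as.character(raw$condition),
                       raw$trial_index, kin, kin_kinetic)
  structure(list(signals = signals, events = events, features = feat,
                 classification = cls),
            class = "snatch_trial")
}

# canonical feature column order of the on-disk feature table
.feature_cols <- c("MvT_duration", "V_avg", "V_max", "Acc_max", "Y_max",
                   "Y_catch", "VTR", "X1", "X2", "X3_DxT", "DxL", "DxV",
                   "vGRF_max", "vGRF_mean_all", "vGRF_mean_jump",
                   "RFD_max_all", "RFD_max_jump", "RFD_mean_all",
                   "RFD_mean_jump", "Power_max_all", "Power_max_jump",
                   "Power_mean_all", "Power_mean_jump")

#' Assemble a one-row feature table
#'
#' @param subject_id,condition,trial_index Trial identity.
#' @param kin Result of [kinematic_features].
#' @param kinetic Result of [kinetic_features].
#'
#' @return One-row data frame with identity columns followed by the 23
#'   parameters in canonical order, plus `jump_detected`.
#' @export
features_row <- function(subject_id, condition, trial_index, kin, kinetic) {
  row <- c(kin, kinetic[setdiff(names(kinetic), "jump_detected")])
  df <- data.frame(subject_id = subject_id, condition = condition,
                   trial_index = as.integer(trial_index),
                   stringsAsFactors = FALSE)
  for (nm in .feature_cols) df[[nm]] <- row[[nm]]
  df$jump_detected <- isTRUE(kinetic$jump_detected)
  df
}

#' @export
print.snatch_trial <- function(x, digits = 2, ...) {
  f <- x$features
  cat(sprintf("snatch_trial: subject %s, condition %s, trial %d\n",
              f$subject_id, f$condition, f$trial_index))
  cat(sprintf("  duration %.2f s | V-max %.2f m/s | Y-max %.1f cm | Y-catch %.1f cm | VTR %.1f cm\n",
              f$MvT_duration, f$V_max, f$Y_max, f$Y_catch, f$VTR))
  cat(sprintf("  X1 %.2f, X2 %.2f, X3 %.2f cm -> pattern (%s) %s\n",
              f$X1, f$X2, f$X3_DxT,
              paste(x$classification$sign_pattern, collapse = ","),
              if (x$classification$is_optimal) "[optimal]" else "[not optimal]"))
  cat(sprintf("  vGRF-max %.2f BW | Power-max %.1f W/kg | flight %s\n",
              f$vGRF_max, f$Power_max_all,
              if (f$jump_detected) "detected" else "not detected"))
  invisible(x)
}

#' Adherence summary of a feature table
#'
#' Counts, per condition, the subjects whose every trial followed the optimal
#' toward-away-toward bar path.
#'
#' @param features Feature table with `subject_id`, `condition`, `X1`, `X2`,
#'   `X3_DxT` columns (rows are trials).
#'
#' @return Data frame with columns `condition`, `n_subjects`,
#'   `n_adherent`.
#' @export
path_adherence <- function(features) {
  opt <- mapply(function(a, b, c) classify_path(a, b, c)$is_optimal,
                features$X1, features$X2, features$X3_DxT)
  out <- lapply(snatch_conditions(), function(cond) {
    sub <- features$condition == cond
    if (!any(sub)) return(NULL)
    adh <- tapply(opt[sub], features$subject_id[sub], subject_adherence)
    data.frame(condition = cond, n_subjects = length(adh),
               n_adherent = sum(adh), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
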