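#' Learning conditions of the study design
#'
#' Factor levels for the four motor-learning conditions: repetitive learning
#' (RL), blocked and serial contextual-interference learning (bCI, sCI) and
#' differential learning (DL).
#'
#' @export
snatch_conditions <- function() c("RL", "bCI", "sCI", "DL")

.as_condition <- function(x) {
  lv <- snatch_conditions()
  if (!all(x %in% lv))
    stop("condition must be one of ", paste(lv, collapse = ", "),
         "; got: ", paste(setdiff(unique(x), lv), collapse = ", "))
  factor(x, levels = lv)
}

.check_series3 <- function(m, what) {
  if (!is.matrix(m) || ncol(m) != 3L)
    stop(what, " must be an n x 3 matrix with columns AP, ML, V")
  if (is.null(colnames(m))) colnames(m) <- c("AP", "ML", "V")
  if (!identical(colnames(m), c("AP", "ML", "V")))
    stop(what, " columns must be named AP, ML, V")
  storage.mode(m) <- "double"
  m
}

#' Raw recording of one snatch trial
#'
#' Bundles the unprocessed two-marker barbell trajectories (metres, canonical
#' frame: AP positive toward the lifter, vertical positive up) and the two
#' force-plate records (newtons) of a single snatch attempt, together with
#' their sampling rates.
#'
#' @param subject_id Subject identifier.
#' @param condition One of `snatch_conditions()`.
#' @param trial_index Trial number within the condition (1..3 in the study
#'   design; larger values are allowed).
#' @param marker_left,marker_right n x 3 matrices (AP, ML, V) in metres.
#' @param f_kin Kinematic sampling rate (Hz).
#' @param plate1,plate2 m x 3 matrices (AP, ML, V) in newtons.
#' @param f_force Force sampling rate (Hz).
#'
#' @return Object of class `raw_trial`.
#' @export
raw_trial <- function(subject_id, condition, trial_index,
                      marker_left, marker_right, f_kin,
                      plate1, plate2, f_force) {
  marker_left <- .check_series3(marker_left, "marker_left")
  marker_right <- .check_series3(marker_right, "marker_right")
  plate1 <- .check_series3(plate1, "plate1")
  plate2 <- .check_series3(plate2, "plate2")
  if (nrow(marker_left) != nrow(marker_right))
    stop("marker series must have equal length")
  if (nrow(plate1) != nrow(plate2))
    stop("plate series must have equal length")
  if (!is.finite(f_kin) || f_kin <= 0 || !is.finite(f_force) || f_force <= 0)
    stop("sampling rates must be positive")
  structure(list(subject_id = as.character(subject_id),
                 condition = .as_condition(condition),
                 trial_index = as.integer(trial_index),
                 marker_left = marker_left, marker_right = marker_right,
                 f_kin = f_kin,
                 plate1 = plate1, plate2 = plate2, f_force = f_force),
            class = "raw_trial")
}

#' @export
print.raw_trial <- function(x, ...) {
  cat(sprintf("raw_trial: subject %s, condition %s, trial %d\n",
              x$subject_id, as.character(x$condition), x$trial_index))
  cat(sprintf("  markers: %d samples @ %g Hz; plates: %d samples @ %g Hz\n",
              nrow(x$marker_left), x$f_kin, nrow(x$plate1), x$f_force))
  invisible(x)
}

#' Static (no-barbell) force record of a subject
#'
#' Quiet-standing record used to measure the subject's accurate body weight.
#'
#' @param subject_id Subject identifier.
#' @param plate1,plate2 m x 3 force matrices (AP, ML, V) in newtons.
#' @param f_force Sampling rate (Hz).
#'
#' @return Object of class `static_record`.
#' @export
static_record <- function(subject_id, plate1, plate2, f_force = 1000) {
  plate1 <- .check_series3(plate1, "plate1")
  plate2 <- .check_series3(plate2, "plate2")
  if (nrow(plate1) != nrow(plate2)) stop("plate series must have equal length")
  if (nrow(plate1) < f_force)
    stop("static record must cover at least 1 s (", f_force, " samples)")
  total_v <- plate1[, "V"] + plate2[, "V"]
  if (any(total_v <= 0))
    stop("static record: total vertical force must be strictly positive; ",
         "check the axis sign convention")
  structure(list(subject_id = as.character(subject_id),
                 plate1 = plate1, plate2 = plate2, f_force = f_force,
                 duration = nrow(plate1) / f_force),
            class = "static_record")
}

#' Subject anthropometrics
#'
#' @param subject_id Subject identifier.
#' @param body_height Standing height (m).
#' @param body_mass Body mass (kg); may be derived from a [static_record] via
#'   [body_weight_from_static].
#'
#' @return Object of class `subject_info`.
#' @export
subject_info <- function(subject_id, body_height, body_mass) {
  if (!is.finite(body_height) || body_height <= 1.0 || body_height >= 2.5)
    stop("body_height must lie in (1.0, 2.5) m")
  if (!is.finite(body_mass) || body_mass <= 30 || body_mass >= 200)
    stop("body_mass must lie in (30, 200) kg")
  structure(list(subject_id = as.character(subject_id),
                 body_height = body_height, body_mass = body_mass),
            class = "subject_info")
}

#' Canonical axis mapping for on-disk channel columns
#'
#' Maps file axis labels to the canonical frame (AP toward the lifter, ML to
#' the lifter's left, V up). A leading minus flips the sign, e.g.
#' `c(AP = "-Y", ML = "X", V = "Z")` for a capture volume whose Y axis points
#' away from the lifter.
#'
#' @param AP,ML,V File axis label (one of "X","Y","Z", optionally prefixed
#'   with "-").
#'
#' @return Named character vector usable by the readers.
#' @export
axis_map <- function(AP = "X", ML = "Y", V = "Z") {
  m <- c(AP = AP, ML = ML, V = V)
  ax <- sub("^-", "", m)
  if (!all(ax %in% c("X", "Y", "Z")) || anyDuplicated(ax))
    stop("axis_map must assign each of X, Y, Z to exactly one canonical axis")
  m
}

# Resolve an axis map against available column suffixes: returns, per canonical
# axis, the source label and sign.
.axis_plan <- function(map) {
  data.frame(canon = names(map),
             src = sub("^-", "", unname(map)),
             sign = ifelse(grepl("^-", unname(map)), -1, 1),
             stringsAsFactors = FALSE)
}
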