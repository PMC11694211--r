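#' Pipeline configuration
#'
#' Collects every tunable threshold of the processing chain in one object.
#' Defaults follow standard practice for barbell biomechanics: a 4th-order
#' zero-phase Butterworth low-pass at 4 Hz for marker trajectories and 15 Hz
#' for force-plate signals, movement start at a sustained vertical barbell
#' velocity of 0.01 m/s, takeoff at a sustained drop of the body-weight
#' normalised vertical ground reaction force below 0.05 BW, and 101-point
#' time normalisation of the start-to-catch phase.
#'
#' @param cutoff_kin Low-pass cutoff for kinematic channels (Hz).
#' @param cutoff_force Low-pass cutoff for force channels (Hz).
#' @param filter_order Butterworth order of a single pass; the forward-backward
#'   application doubles the effective order.
#' @param start_velocity_threshold Vertical barbell velocity defining movement
#'   start (m/s).
#' @param start_sustain Time the start threshold must be held for the crossing
#'   to count (s); rejects single-sample noise spikes.
#' @param takeoff_force_threshold Fraction of body weight below which the
#'   lifter is considered airborne.
#' @param takeoff_sustain Time the takeoff threshold must be held (s).
#' @param rfd_interval Sampling interval used for rate of force development
#'   (s); equals the force-plate sampling period.
#' @param n_time_points Number of points of the time-normalised curves.
#' @param stats_unit Unit of analysis for the statistical battery:
#'   `"subject_mean"` (mean of a subject's trials per condition) or `"trial"`.
#' @param alpha Significance level used throughout.
#' @param gravity Gravitational acceleration (m/s^2) used to convert weight to
#'   mass and to express power per kilogram.
#'
#' @return An object of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$cutoff_kin
pipeline_config <- function(cutoff_kin = 4,
                            cutoff_force = 15,
                            filter_order = 4,
                            start_velocity_threshold = 0.01,
                            start_sustain = 0.04,
                            takeoff_force_threshold = 0.05,
                            takeoff_sustain = 0.02,
                            rfd_interval = 0.001,
                            n_time_points = 101,
                            stats_unit = c("subject_mean", "trial"),
                            alpha = 0.05,
                            gravity = 9.81) {
  stats_unit <- match.arg(stats_unit)
  num_pos <- c(cutoff_kin = cutoff_kin, cutoff_force = cutoff_force,
               filter_order = filter_order,
               start_velocity_threshold = start_velocity_threshold,
               start_sustain = start_sustain,
               takeoff_force_threshold = takeoff_force_threshold,
               takeoff_sustain = takeoff_sustain,
               rfd_interval = rfd_interval, gravity = gravity)
  bad <- names(num_pos)[!is.finite(num_pos) | num_pos <= 0]
  if (length(bad))
    stop("pipeline_config: these fields must be positive numbers: ",
         paste(bad, collapse = ", "))
  if (n_time_points < 2)
    stop("pipeline_config: n_time_points must be >= 2")
  if (alpha <= 0 || alpha >= 1)
    stop("pipeline_config: alpha must lie in (0, 1)")
  structure(list(cutoff_kin = cutoff_kin, cutoff_force = cutoff_force,
                 filter_order = as.integer(filter_order),
                 start_velocity_threshold = start_velocity_threshold,
                 start_sustain = start_sustain,
                 takeoff_force_threshold = takeoff_force_threshold,
                 takeoff_sustain = takeoff_sustain,
                 rfd_interval = rfd_interval,
                 n_time_points = as.integer(n_time_points),
                 stats_unit = stats_unit, alpha = alpha, gravity = gravity),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Snatch pipeline configuration\n")
  cat(sprintf("  filters      : Butterworth order %d (zero-phase), %g Hz kin / %g Hz force\n",
              x$filter_order, x$cutoff_kin, x$cutoff_force))
  cat(sprintf("  start        : v >= %g m/s sustained %g s\n",
              x$start_velocity_threshold, x$start_sustain))
  cat(sprintf("  takeoff      : vGRF < %g BW sustained %g s\n",
              x$takeoff_force_threshold, x$takeoff_sustain))
  cat(sprintf("  time norm    : %d points; stats unit: %s; alpha = %g\n",
              x$n_time_points, x$stats_unit, x$alpha))
  invisible(x)
}
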