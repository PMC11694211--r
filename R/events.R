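#' Phase events of a snatch trial
#'
#' Container for the sample indices of the movement phases: start (sustained
#' vertical barbell velocity above threshold), most-rearward point of the pull
#' (toward the lifter), peak bar height, most-forward point of the turnover
#' (away from the lifter), catch (first zero vertical velocity after the
#' descent from peak height), all on the kinematic timebase, and takeoff
#' (flight onset) on the force timebase (`NA` when no flight is detected).
#'
#' @param start_idx,rearmost_idx,ymax_idx,foremost_idx,catch_idx Kinematic
#'   sample indices.
#' @param takeoff_idx Force sample index or `NA`.
#'
#' @return Object of class `phase_events`.
#' @export
phase_events <- function(start_idx, ymax_idx, catch_idx,
                         rearmost_idx = NA_integer_,
                         foremost_idx = NA_integer_,
                         takeoff_idx = NA_integer_) {
  if (!(start_idx < ymax_idx && ymax_idx < catch_idx))
    stop("phase_events: need start_idx < ymax_idx < catch_idx")
  if (!is.na(rearmost_idx) &&
      (rearmost_idx < start_idx || rearmost_idx > ymax_idx))
    stop("phase_events: rearmost_idx must lie in [start_idx, ymax_idx]")
  if (!is.na(foremost_idx) && !is.na(rearmost_idx) &&
      (foremost_idx < rearmost_idx || foremost_idx > catch_idx))
    stop("phase_events: foremost_idx must lie in [rearmost_idx, catch_idx]")
  structure(list(start_idx = as.integer(start_idx),
                 rearmost_idx = as.integer(rearmost_idx),
                 ymax_idx = as.integer(ymax_idx),
                 foremost_idx = as.integer(foremost_idx),
                 catch_idx = as.integer(catch_idx),
                 takeoff_idx = as.integer(takeoff_idx)),
            class = "phase_events")
}

#' @export
print.phase_events <- function(x, ...) {
  cat(sprintf(
    "phase_events: start %d, rearmost %s, ymax %d, foremost %s, catch %d, takeoff %s\n",
    x$start_idx, x$rearmost_idx, x$ymax_idx, x$foremost_idx, x$catch_idx,
    ifelse(is.na(x$takeoff_idx), "none", x$takeoff_idx)))
  invisible(x)
}

#' Detect movement start
#'
#' First sample at which the vertical barbell velocity reaches the start
#' threshold (0.01 m/s by default) and stays at or above it for the sustain
#' window, so that single-sample noise spikes are rejected.
#'
#' @param vvel Vertical barbell velocity (m/s), kinematic timebase.
#' @param f_kin Sampling rate (Hz).
#' @param cfg A [pipeline_config].
#'
#' @return Start sample index.
#' @export
detect_start <- function(vvel, f_kin, cfg = pipeline_config()) {
  thr <- cfg$start_velocity_threshold
  win <- max(1L, as.integer(round(cfg$start_sustain * f_kin)))
  above <- vvel >= thr
  r <- rle(above)
  starts <- cumsum(r$lengths) - r$lengths + 1L
  ok <- which(r$values & r$lengths >= win)
  if (!length(ok))
    stop("detect_start: no movement detected (velocity never sustained above ",
         thr, " m/s)")
  starts[ok[1]]
}

#' Detect peak height and catch
#'
#' Peak bar height is the maximum vertical position after the start. The
#' catch is the first instant at which the vertical velocity returns to >= 0
#' after the phase of negative velocity that follows peak height.
#'
#' @param vpos Vertical barbell position (m), baseline-subtracted.
#' @param vvel Vertical barbell velocity (m/s).
#' @param start_idx Movement start index.
#'
#' @return List with `ymax_idx` and `catch_idx`.
#' @export
detect_catch <- function(vpos, vvel, start_idx) {
  n <- length(vpos)
  if (start_idx < 1 || start_idx >= n) stop("detect_catch: invalid start_idx")
  ymax_idx <- as.integer(start_idx) - 1L + which.max(vpos[start_idx:n])
  after <- if (ymax_idx < n) vvel[(ymax_idx + 1L):n] else numeric(0)
  neg <- which(after < 0)
  if (!length(neg))
    stop("detect_catch: no catch detected (no negative-velocity phase after peak height)")
  first_neg <- neg[1]
  nonneg <- which(after[-seq_len(first_neg)] >= 0)
  if (!length(nonneg))
    stop("detect_catch: no catch detected (velocity never returns to zero)")
  catch_idx <- ymax_idx + first_neg + nonneg[1]
  list(ymax_idx = ymax_idx, catch_idx = as.integer(catch_idx))
}

#' Detect takeoff (flight onset)
#'
#' First force-timebase sample after movement start at which the body-weight
#' normalised vGRF drops below the takeoff threshold (0.05 BW by default) and
#' stays below it for the sustain window. Absence of flight is a valid
#' outcome and returns `NA`.
#'
#' @param vgrf_bw vGRF in body-weight multiples, force timebase.
#' @param f_force Force sampling rate (Hz).
#' @param start_force_idx Force-timebase index of movement start.
#' @param cfg A [pipeline_config].
#'
#' @return Takeoff sample index, or `NA_integer_` if no flight is detected.
#' @export
detect_takeoff <- function(vgrf_bw, f_force, start_force_idx = 1L,
                           cfg = pipeline_config()) {
  thr <- cfg$takeoff_force_threshold
  win <- max(1L, as.integer(round(cfg$takeoff_sustain * f_force)))
  idx <- seq(from = max(1L, start_force_idx), to = length(vgrf_bw))
  below <- vgrf_bw[idx] < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= win)
  if (!length(ok)) return(NA_integer_)
  as.integer(idx[1] - 1L + starts[ok[1]])
}

# Interior turning points (local extrema) of a smooth series on [from, to].
# Low-prominence wiggles are pruned: the alternating sequence of boundary and
# extremum values is simplified by repeatedly removing the smallest swing
# below `prominence` (both extrema of an interior wiggle, or the lone
# extremum of a boundary-adjacent one).
.turning_points <- function(x, from, to, prominence = 0) {
  if (to - from < 2) return(integer(0))
  seg <- x[from:to]
  d <- diff(seg)
  s <- sign(d)
  # carry the previous direction through flat stretches
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  tp <- which(s[-1] != 0 & s[-length(s)] != 0 & s[-1] != s[-length(s)]) + 1L
  if (length(tp) && prominence > 0) {
    repeat {
      z <- c(seg[1], seg[tp], seg[length(seg)])
      sw <- abs(diff(z))
      # the swing away from the start baseline is never pruned: the first
      # excursion may genuinely be shallow (X1 near zero), whereas wiggles on
      # the settling tail are not path structure
      sw[1] <- Inf
      j <- which.min(sw)
      if (sw[j] >= prominence) break
      # swing j runs from point j to j+1 of z; interior points are tp indices
      drop <- intersect(c(j - 1L, j), seq_along(tp))
      tp <- tp[-drop]
      if (!length(tp)) break
    }
  }
  from - 1L + tp
}

#' Anteroposterior extremes X1, X2, X3
#'
#' Locates the rearmost point of the pull (toward the lifter) and the most
#' forward point of the turnover (away from the lifter) on the
#' baseline-subtracted AP trajectory, and reads off the three net horizontal
#' displacements: X1 at the pull extreme, X2 at the turnover extreme and X3
#' at the catch, signed in the canonical frame (positive toward the lifter)
#' and reported in centimetres.
#'
#' The extremes are identified as turning points (interior local extrema) of
#' the smoothed AP trace between start and catch: the turnover extreme X2 is
#' the last turning point before the catch (the bar sweeps away and then
#' loops forward into the catch), and the pull extreme X1 is the turning
#' point immediately preceding it; an earlier away-drift during the first
#' pull is thereby ignored. Turning points with an excursion below
#' `prominence` are pruned first, so the rule reads the gross bar path, not
#' residual wiggles. This ordinal rule keeps X1 signed (it may be
#' negative when the bar never returns behind its start line, as in
#' beginners) and makes mirroring the AP axis flip all three signs exactly,
#' which a max/min-over-window rule cannot do. When the path has too few
#' turning points the most displaced sample of the remaining window is used
#' instead.
#'
#' @param appos Baseline-subtracted AP position (m), start value 0.
#' @param events List or [phase_events] with `start_idx`, `ymax_idx`,
#'   `catch_idx`.
#' @param prominence Minimum excursion (m) for a turning point to count
#'   (default 5 mm; suppresses residual noise and filter-ringing wiggles,
#'   which are an order of magnitude below the bar-path excursions).
#'
#' @return List with `rearmost_idx`, `foremost_idx`, `x1_cm`, `x2_cm`,
#'   `x3_cm`.
#' @export
horizontal_extremes <- function(appos, events, prominence = 0.005) {
  s <- events$start_idx; ym <- events$ymax_idx; ct <- events$catch_idx
  if (!(s < ym && ym < ct)) stop("horizontal_extremes: empty phase window")
  tp <- .turning_points(appos, s, ct, prominence)
  if (length(tp) >= 2) {
    foremost_idx <- tp[length(tp)]
    rearmost_idx <- tp[length(tp) - 1L]
  } else if (length(tp) == 1) {
    foremost_idx <- tp
    w <- s:tp
    rearmost_idx <- w[which.max(abs(appos[w] - appos[s]))]
  } else {
    w <- s:ct
    rearmost_idx <- w[which.max(abs(appos[w] - appos[s]))]
    w2 <- rearmost_idx:ct
    foremost_idx <- w2[which.max(abs(appos[w2] - appos[rearmost_idx]))]
  }
  list(rearmost_idx = as.integer(rearmost_idx),
       foremost_idx = as.integer(foremost_idx),
       x1_cm = 100 * appos[rearmost_idx],
       x2_cm = 100 * appos[foremost_idx],
       x3_cm = 100 * appos[ct])
}

#' Segment all phase events of a trial
#'
#' Runs [detect_start], [detect_catch], [horizontal_extremes] and
#' [detect_takeoff] on preprocessed signals and assembles a [phase_events]
#' object.
#'
#' @param pos n x 2 (AP, V) baseline-subtracted position (m).
#' @param vel n x 2 velocity (m/s).
#' @param vgrf_bw vGRF in BW on the force timebase.
#' @param f_kin,f_force Sampling rates (Hz).
#' @param cfg A [pipeline_config].
#'
#' @return A [phase_events] object.
#' @export
segment_phases <- function(pos, vel, vgrf_bw, f_kin, f_force,
                           cfg = pipeline_config()) {
  start_idx <- detect_start(vel[, "V"], f_kin, cfg)
  yc <- detect_catch(pos[, "V"], vel[, "V"], start_idx)
  hx <- horizontal_extremes(pos[, "AP"],
                            list(start_idx = start_idx, ymax_idx = yc$ymax_idx,
                                 catch_idx = yc$catch_idx))
  start_force <- 1L + as.integer(round((start_idx - 1) / f_kin * f_force))
  takeoff <- detect_takeoff(vgrf_bw, f_force, start_force, cfg)
  phase_events(start_idx = start_idx, ymax_idx = yc$ymax_idx,
               catch_idx = yc$catch_idx, rearmost_idx = hx$rearmost_idx,
               foremost_idx = hx$foremost_idx, takeoff_idx = takeoff)
}
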