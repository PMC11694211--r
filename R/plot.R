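#' Plot a processed snatch trial
#'
#' Two panels: the barbell path in the sagittal plane (AP vs vertical, with
#' the start, pull extreme X1, turnover extreme X2, peak height and catch
#' marked) and the body-weight normalised vGRF over time with the phase
#' events.
#'
#' @param x A `snatch_trial` from [process_trial].
#' @param ... Passed to `plot`.
#' @export
plot.snatch_trial <- function(x, ...) {
  sg <- x$signals; ev <- x$events
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  win <- ev$start_idx:ev$catch_idx
  ap <- 100 * sg$pos[win, "AP"]; v <- 100 * sg$pos[win, "V"]
  graphics::plot(ap, v, type = "l", xlab = "AP displacement (cm, + toward lifter)",
                 ylab = "height (cm)", main = "barbell path", ...)
  marks <- c(start = ev$start_idx, X1 = ev$rearmost_idx, X2 = ev$foremost_idx,
             Ymax = ev$ymax_idx, catch = ev$catch_idx)
  graphics::points(100 * sg$pos[marks, "AP"], 100 * sg$pos[marks, "V"],
                   pch = 19, col = "firebrick")
  graphics::text(100 * sg$pos[marks, "AP"], 100 * sg$pos[marks, "V"],
                 names(marks), pos = 4, cex = 0.8)
  tf <- (seq_along(sg$vgrf_bw) - 1) / sg$f_force
  graphics::plot(tf, sg$vgrf_bw, type = "l", xlab = "time (s)",
                 ylab = "vGRF (BW)", main = "ground reaction force")
  evt <- c(ev$start_idx, ev$catch_idx) / sg$f_kin
  graphics::abline(v = evt, lty = 2, col = "grey40")
  if (!is.na(ev$takeoff_idx))
    graphics::abline(v = (ev$takeoff_idx - 1) / sg$f_force, lty = 3,
                     col = "firebrick")
  invisible(x)
}

#' Plot one variable of a study across conditions
#'
#' Per-condition boxplots of the unit-of-analysis values of one parameter.
#'
#' @param x A `snatch_study` (used only for unit/alpha annotation).
#' @param features The trial-level feature table the study was fitted on.
#' @param variable Feature column to show.
#' @param ... Passed to `boxplot`.
#' @export
plot.snatch_study <- function(x, features, variable = "V_max", ...) {
  tab <- variable_table(features, variable, x$unit)
  graphics::boxplot(as.data.frame(tab), xlab = "learning condition",
                    ylab = variable,
                    main = sprintf("%s by condition (%s)", variable, x$unit),
                    ...)
  invisible(x)
}
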