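#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass forward and backward
#' (zero-phase; the effective attenuation order doubles, so a sine exactly at
#' the cutoff leaves with amplitude ~0.5 rather than 1/sqrt(2)). The series is
#' extended at both ends by odd reflection and each pass removes the local DC
#' level before filtering, which suppresses the start-up transients a plain
#' forward-backward pass produces on signals that do not begin or end at zero.
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz).
#' @param cutoff Cutoff frequency (Hz); must be below the Nyquist rate.
#' @param order Filter order of a single pass.
#'
#' @return Filtered series, same length as `x`. DC gain is exactly 1.
#' @export
#' @examples
#' butter_lowpass(rep(2, 100), fs = 250, cutoff = 4)[1]  # 2: DC preserved
butter_lowpass <- function(x, fs, cutoff, order = 4) {
  n <- length(x)
  if (!is.finite(fs) || !is.finite(cutoff) || fs <= 2 * cutoff)
    stop("butter_lowpass: need fs > 2 * cutoff")
  minlen <- 3L * as.integer(order) + 1L
  if (n < minlen)
    stop("butter_lowpass: series too short for filter warm-up; need at least ",
         minlen, " samples, got ", n)
  ba <- signal::butter(order, cutoff / (fs / 2), type = "low")
  pad <- min(n - 1L, max(12L, 3L * as.integer(ceiling(fs / cutoff))))
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  one_pass <- function(z) {
    z0 <- z[1]
    as.numeric(signal::filter(ba, z - z0)) + z0
  }
  y <- one_pass(xe)
  y <- rev(one_pass(rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Numerical differentiation
#'
#' Central differences on the interior, one-sided differences at the two ends;
#' output has the same length as the input.
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz).
#'
#' @return Derivative series (units of `x` per second).
#' @export
differentiate <- function(x, fs) {
  n <- length(x)
  if (n < 3) stop("differentiate: need at least 3 samples")
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d
}

#' Time-normalise a phase of a series
#'
#' Linearly interpolates `x` between `start_idx` and `catch_idx` onto
#' `n_points` equally spaced time fractions (0..100% of the movement). The
#' first and last values are preserved exactly.
#'
#' @param x Numeric series.
#' @param start_idx,catch_idx Sample indices delimiting the phase.
#' @param n_points Number of output points (default 101).
#'
#' @return Numeric vector of length `n_points`.
#' @export
time_normalize <- function(x, start_idx, catch_idx, n_points = 101) {
  if (start_idx >= catch_idx)
    stop("time_normalize: start_idx must be smaller than catch_idx")
  if (n_points < 2) stop("time_normalize: n_points must be >= 2")
  idx <- seq(start_idx, catch_idx, length.out = n_points)
  out <- stats::approx(x = seq_along(x), y = x, xout = idx)$y
  out[1] <- x[start_idx]
  out[n_points] <- x[catch_idx]
  out
}
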