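#' A-priori power of a one-way repeated-measures ANOVA
#'
#' Power of the within-factor F test computed from the noncentral F
#' distribution with noncentrality lambda = f^2 * n * m * epsilon / (1 - rho),
#' numerator df (m - 1) * epsilon and denominator df (n - 1) * (m - 1) *
#' epsilon, where f is Cohen's effect size, m the number of repeated
#' measurements, rho the assumed correlation among them and epsilon the
#' nonsphericity correction (1 = sphericity). This is the standard
#' computation used for a-priori sample-size planning of within-subject
#' designs.
#'
#' @param f Cohen's effect size (>= 0).
#' @param n Sample size (>= 2); may be a vector.
#' @param m Number of repeated measurements (>= 2).
#' @param alpha Type-I error level.
#' @param rho Correlation among repeated measures, in [0, 1).
#' @param epsilon Nonsphericity correction, in (0, 1].
#'
#' @return Power value(s) in (0, 1). With `f = 0` the power equals `alpha`.
#' @export
#' @examples
#' rmanova_power(f = 0.5, n = 10, m = 4, rho = 0.5)  # 0.951
rmanova_power <- function(f, n, m, alpha = 0.05, rho = 0.5, epsilon = 1) {
  if (!is.finite(f) || f < 0) stop("rmanova_power: f must be >= 0")
  if (any(!is.finite(n)) || any(n < 2)) stop("rmanova_power: n must be >= 2")
  if (m < 2) stop("rmanova_power: m must be >= 2")
  if (alpha <= 0 || alpha >= 1) stop("rmanova_power: alpha must lie in (0, 1)")
  if (rho < 0 || rho >= 1) stop("rmanova_power: rho must lie in [0, 1)")
  if (epsilon <= 0 || epsilon > 1) stop("rmanova_power: epsilon must lie in (0, 1]")
  lambda <- f^2 * n * m * epsilon / (1 - rho)
  df1 <- (m - 1) * epsilon
  df2 <- (n - 1) * (m - 1) * epsilon
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Minimum sample size for a target power
#'
#' Smallest integer n whose repeated-measures ANOVA power (see
#' [rmanova_power]) reaches the target. The result is the exact argmin:
#' power(n - 1) < target <= power(n).
#'
#' @inheritParams rmanova_power
#' @param target_power Desired power, in (0, 1).
#' @param n_max Upper bound of the search.
#'
#' @return Integer sample size.
#' @export
#' @examples
#' min_sample_size(f = 0.5, target_power = 0.95, m = 4, rho = 0.5)  # 10
min_sample_size <- function(f, target_power, m, alpha = 0.05, rho = 0.5,
                            epsilon = 1, n_max = 1000) {
  if (target_power <= 0 || target_power >= 1)
    stop("min_sample_size: target_power must lie in (0, 1)")
  for (n in 2:n_max) {
    if (rmanova_power(f, n, m, alpha, rho, epsilon) >= target_power)
      return(as.integer(n))
  }
  stop(sprintf(
    "min_sample_size: target power %.3f not attainable below n = %d (power there: %.4f)",
    target_power, n_max, rmanova_power(f, n_max, m, alpha, rho, epsilon)))
}
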