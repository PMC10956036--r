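# Noncentral-F power for a tested predictor in multiple regression
# (Cohen's f^2 effect size; noncentrality lambda = f^2 * n).

#' Power of a regression-coefficient test at a given sample size
#'
#' Probability that a noncentral F statistic with df1 = `p_tested`,
#' df2 = n - `p_total` - 1 and noncentrality `f2 * n` exceeds the central-F
#' critical value at `alpha`.
#'
#' @param f2 Cohen's f-squared effect size (> 0; as f2 tends to 0 the power
#'   tends to alpha).
#' @param n sample size.
#' @param alpha significance level (default 0.05).
#' @param p_total total number of predictors in the model (default 5: three
#'   symptom dimensions plus age and gender).
#' @param p_tested number of coefficients under test (default 1).
#' @return power in (0, 1).
#' @export
power_for_n <- function(f2, n, alpha = 0.05, p_total = 5L, p_tested = 1L) {
  stopifnot(f2 >= 0, alpha > 0, alpha < 1, p_tested >= 1)
  df2 <- n - p_total - 1
  if (df2 <= 0) stop("df2 = n - p_total - 1 must be positive")
  fcrit <- stats::qf(1 - alpha, p_tested, df2)
  stats::pf(fcrit, p_tested, df2, ncp = f2 * n, lower.tail = FALSE)
}

#' Smallest sample size reaching a target power
#'
#' Monotone search for the smallest integer n with
#' `power_for_n(f2, n, ...) >= target_power`.
#'
#' @param f2 Cohen's f-squared (> 0).
#' @param target_power target power in (0, 1).
#' @param alpha,p_total,p_tested see [power_for_n()].
#' @return integer sample size.
#' @export
required_n <- function(f2, target_power = 0.80, alpha = 0.05,
                       p_total = 5L, p_tested = 1L) {
  stopifnot(f2 > 0, target_power > 0, target_power < 1)
  lo <- p_total + 2L
  hi <- lo
  while (power_for_n(f2, hi, alpha, p_total, p_tested) < target_power) {
    hi <- hi * 2L
    if (hi > 1e6) stop("target power unreachable at n <= 1e6")
  }
  while (hi - lo > 0L) {
    mid <- (lo + hi) %/% 2L
    if (power_for_n(f2, mid, alpha, p_total, p_tested) >= target_power) hi <- mid
    else lo <- mid + 1L
  }
  hi
}
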