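#' Power of the chi-square test
#'
#' Power of a chi-square test with `df` degrees of freedom at Cohen's
#' effect size `w` and sample size `n`: the test statistic follows the
#' noncentral chi-square distribution with noncentrality
#' \eqn{\lambda = n w^2}, so
#' \deqn{power = P[\,\chi^2_{df}(\lambda) > \chi^2_{df, 1-\alpha}\,].}
#' At `w = 0` the alternative equals the null and power is exactly
#' `alpha`. Here `n` is the count of informative individuals — the same N
#' that enters [freq_asym_test()] after symmetric specimens are dropped.
#'
#' @param w Cohen's chi-square effect size, `w >= 0` (dimensionless; for
#'   a 50:50 frequency test with left-larger proportion p,
#'   \eqn{w = |2p - 1|}).
#' @param n sample size (informative individuals), `n >= 1`. Vectorized
#'   over `w` and `n`.
#' @param df degrees of freedom (default 1).
#' @param alpha significance level (default 0.05).
#' @return Power, a probability in \[`alpha`, 1).
#' @examples
#' chisq_power(0.25, 60)   # just under 0.5
#' chisq_power(0, 100)     # exactly alpha
#' @export
chisq_power <- function(w, n, df = 1, alpha = 0.05) {
  .check(all(w >= 0), "effect size w must be non-negative")
  .check(all(n >= 1), "sample size must be at least 1")
  .check(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  crit <- stats::qchisq(1 - alpha, df = df)
  lambda <- n * w^2
  out <- stats::pchisq(crit, df = df, ncp = lambda, lower.tail = FALSE)
  # lambda = 0 is the null: power is alpha by definition, exactly
  out[lambda == 0] <- alpha
  out
}

#' Smallest sample size reaching a target power
#'
#' Inverts [chisq_power()] over integer `n`: returns the smallest N with
#' `power(N) > target_power` (and `power(N - 1) <= target_power`), found
#' by exponential bracketing plus bisection. Power is strictly increasing
#' in N for `w > 0`, so the answer is unique.
#'
#' @param w effect size, strictly positive (at `w = 0` no finite N
#'   reaches any target above `alpha`).
#' @param df,alpha as in [chisq_power()].
#' @param target_power the power to exceed (default 0.50).
#' @return The required integer sample size.
#' @examples
#' chisq_power_n(0.25, target_power = 0.50)
#' @export
chisq_power_n <- function(w, df = 1, alpha = 0.05, target_power = 0.50) {
  .check(w > 0, "no finite sample size reaches the target when w = 0")
  .check(target_power < 1, "target power must be below 1")
  if (target_power < alpha || chisq_power(w, 1, df, alpha) > target_power)
    return(1L)
  lo <- 1L; hi <- 2L
  while (chisq_power(w, hi, df, alpha) <= target_power) {
    lo <- hi
    hi <- hi * 2L
    .check(hi < 2^30, "target power unreachable at any feasible n")
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (chisq_power(w, mid, df, alpha) > target_power) hi <- mid
    else lo <- mid
  }
  hi
}

#' Power table over effect-size and sample-size grids
#'
#' Tabulates [chisq_power()] over a grid, in long format ready for
#' plotting or CSV export. Defaults follow the planning convention of
#' scanning effect sizes 0 to 0.5 in steps of 0.05 at `df = 1`,
#' `alpha = 0.05`.
#'
#' @param w effect-size grid.
#' @param n sample-size grid.
#' @param df,alpha as in [chisq_power()].
#' @return Data frame with columns `w`, `n`, `power`, one row per
#'   combination (w varying slowest).
#' @export
chisq_power_table <- function(w = seq(0, 0.5, by = 0.05),
                              n = c(20, 40, 60, 80, 100, 150, 200),
                              df = 1, alpha = 0.05) {
  .check(length(w) > 0 && length(n) > 0, "grids must be non-empty")
  g <- expand.grid(n = n, w = w)[, c("w", "n")]
  g$power <- chisq_power(g$w, g$n, df = df, alpha = alpha)
  rownames(g) <- NULL
  g
}
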