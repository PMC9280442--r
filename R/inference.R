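#' Frequency test for left- versus right-larger counts
#'
#' Tests whether the numbers of left-larger and right-larger individuals
#' in a sample deviate from 50:50, excluding symmetric individuals. The
#' default statistic is a continuity-corrected chi-square on the 2x2
#' table whose first row is the observed counts \eqn{(n_L, n_R)} and
#' whose second row is the equal-split expectation \eqn{(E, E)} with
#' \eqn{E = (n_L + n_R)/2} (which may be half-integral). Cell
#' expectations \eqn{\hat E} are taken from the table margins and the
#' Yates-corrected statistic
#' \deqn{\chi^2_1 = \sum_{cells} (\,|O - \hat E| - 0.5\,)^2 / \hat E}
#' is referred to the chi-square distribution with 1 df, clamping
#' \eqn{|O - \hat E| - 0.5} at zero. This construction is roughly half as
#' large as the plain one-sample goodness-of-fit
#' \eqn{\sum (O - E)^2 / E} and makes the test conservative; the
#' continuity correction also forces \eqn{\chi^2 = 0} whenever the counts
#' differ by at most 1. An exact two-tailed binomial test and the
#' uncorrected goodness-of-fit are available as labelled alternatives.
#'
#' @param n_left,n_right counts of left-larger and right-larger
#'   individuals (symmetric individuals already excluded);
#'   `n_left + n_right >= 1`.
#' @param method `"continuity"` (default, described above), `"binomial"`
#'   (exact test, `p = 0.5`), or `"gof"` (uncorrected one-sample
#'   goodness-of-fit).
#' @return An object of classes `freq_asym_test` and `htest` with
#'   `statistic` (chi-square; `NA` for the binomial test), `parameter`
#'   (df = 1), `p.value` (two-tailed), `estimate` (the two counts) and
#'   `expected` (the per-side expectation E).
#' @examples
#' freq_asym_test(48, 70)   # chi^2 = 1.71, p = .191
#' freq_asym_test(23, 51)   # chi^2 = 4.74, p = .030
#' @export
freq_asym_test <- function(n_left, n_right,
                           method = c("continuity", "binomial", "gof")) {
  method <- match.arg(method)
  .check(length(n_left) == 1L && length(n_right) == 1L &&
           is.finite(n_left) && is.finite(n_right) &&
           n_left >= 0 && n_right >= 0,
         "n_left and n_right must be single non-negative counts")
  n <- n_left + n_right
  .check(n >= 1, "no informative (asymmetric) individuals: cannot test")
  E <- n / 2
  if (method == "continuity") {
    obs <- rbind(c(n_left, n_right), c(E, E))
    Ehat <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    stat <- sum(pmax(abs(obs - Ehat) - 0.5, 0)^2 / Ehat)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    meth <- "Continuity-corrected chi-square on observed vs 50:50 expected counts"
  } else if (method == "gof") {
    stat <- (n_left - E)^2 / E + (n_right - E)^2 / E
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    meth <- "Uncorrected chi-square goodness of fit against 50:50"
  } else {
    stat <- NA_real_
    p <- stats::binom.test(n_left, n, p = 0.5)$p.value
    meth <- "Exact two-tailed binomial test against 50:50"
  }
  structure(list(
    statistic = c("X-squared" = unname(stat)),
    parameter = c(df = 1),
    p.value = p,
    estimate = c(n_left_larger = n_left, n_right_larger = n_right),
    expected = E,
    method = meth,
    alternative = "two.sided",
    data.name = sprintf("%g left-larger vs %g right-larger", n_left, n_right)),
    class = c("freq_asym_test", "htest"))
}

#' Paired magnitude test for bilateral sizes
#'
#' Two-tailed paired t-test of whether one side of a bilateral element is
#' systematically larger: differences \eqn{d_i = right_i - left_i}, so a
#' positive t means right-larger, matching the sign of mean percent
#' asymmetry. All usable pairs enter, including exactly symmetric ones
#' (df = N - 1 with N counting symmetric individuals). By default the
#' test runs on raw lengths in mm; `on = "pa"` instead tests the
#' per-individual percent-asymmetry values against zero, which weights
#' every specimen equally regardless of its size. The mean and SD of the
#' percent-asymmetry values are always returned for reporting.
#'
#' @param left,right paired length vectors in mm (same specimens, same
#'   order), N >= 2.
#' @param on `"lengths"` (default) or `"pa"`.
#' @return A list of class `magnitude_test`: `t`, `df`, `p.value`,
#'   `mean_pa`, `sd_pa`, `n`, `on`. When all differences are identical
#'   (zero variance) the t statistic is undefined and `t`/`p.value` are
#'   `NA`.
#' @export
magnitude_test <- function(left, right, on = c("lengths", "pa")) {
  on <- match.arg(on)
  .check(length(left) == length(right), "left and right must be paired")
  ok <- is.finite(left) & is.finite(right)
  left <- left[ok]; right <- right[ok]
  n <- length(left)
  .check(n >= 2L, "need at least two pairs")
  pa <- percent_asymmetry(left, right)
  d <- if (on == "lengths") right - left else pa
  if (stats::sd(d) == 0) {
    t <- NA_real_; p <- NA_real_
  } else {
    tt <- stats::t.test(d)  # one-sample on differences == paired t
    t <- unname(tt$statistic); p <- tt$p.value
  }
  structure(list(t = t, df = n - 1L, p.value = p,
                 mean_pa = mean(pa), sd_pa = stats::sd(pa),
                 n = n, on = on),
            class = "magnitude_test")
}

#' @export
print.magnitude_test <- function(x, ...) {
  cat("Paired magnitude test (on ", x$on, "), N = ", x$n, "\n",
      "  t[", x$df, "] = ",
      if (is.na(x$t)) "undefined (zero variance)"
      else sprintf("%.2f, p = %s", x$t, format_p(x$p.value)),
      "\n  mean PA = ", sprintf("%.2f%% (SD %.2f)", x$mean_pa, x$sd_pa),
      "\n", sep = "")
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests number of tests in the family (one family per
#'   statistical approach, e.g. 9 taxon x element comparisons).
#' @param family_alpha family-wise error rate, default 0.05.
#' @return `family_alpha / n_tests` (0.05/9 = 0.006 at 3 decimals).
#' @export
bonferroni_alpha <- function(n_tests, family_alpha = 0.05) {
  .check(n_tests >= 1, "n_tests must be at least 1")
  family_alpha / n_tests
}

#' Per-group asymmetry summary table
#'
#' Runs the frequency test and the magnitude test for every
#' taxon x element group of an asymmetry-record table and assembles one
#' summary row per group: the published-table layout (N, direction
#' counts, chi-square and p, mean and SD of percent asymmetry, paired t
#' and p) plus significance flags at the raw alpha and at the
#' Bonferroni-corrected alpha.
#'
#' @param records output of [asymmetry_records()] (filters applied).
#' @param alpha raw per-test significance level (default 0.05).
#' @param n_tests size of the Bonferroni family per statistical approach;
#'   default is the number of groups actually summarized.
#' @param t_on passed to [magnitude_test()] (`"lengths"` or `"pa"`).
#' @return Data frame with one row per group: `taxon`, `element`, `n`,
#'   `n_left_larger`, `n_right_larger`, `n_symmetric`, `chi2`, `chi2_p`,
#'   `mean_pa`, `sd_pa`, `t`, `t_df`, `t_p`, and logical flags
#'   `freq_sig_raw`, `freq_sig_bonf`, `mag_sig_raw`, `mag_sig_bonf`. A
#'   fully symmetric group (no left- or right-larger individuals) gets
#'   `NA` chi-square. The attribute `bonferroni_alpha` carries the
#'   corrected threshold.
#' @export
summarize_asymmetry <- function(records, alpha = 0.05, n_tests = NULL,
                                t_on = c("lengths", "pa")) {
  t_on <- match.arg(t_on)
  counts <- asymmetry_counts(records)
  .check(nrow(counts) > 0L, "no usable records to summarize")
  if (is.null(n_tests)) n_tests <- nrow(counts)
  bonf <- bonferroni_alpha(n_tests, alpha)
  x <- records[!records$excluded & !is.na(records$percent_asymmetry), ]
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    ci <- counts[i, ]
    g <- x[x$taxon == ci$taxon & x$element == ci$element, ]
    if (ci$n_left_larger + ci$n_right_larger >= 1) {
      ft <- freq_asym_test(ci$n_left_larger, ci$n_right_larger)
      chi2 <- unname(ft$statistic); chi2_p <- ft$p.value
    } else {
      chi2 <- NA_real_; chi2_p <- NA_real_
    }
    mt <- if (nrow(g) >= 2L) magnitude_test(g$left_length, g$right_length,
                                            on = t_on)
          else list(t = NA_real_, df = nrow(g) - 1L, p.value = NA_real_,
                    mean_pa = mean(g$percent_asymmetry),
                    sd_pa = NA_real_)
    cbind(ci,
          data.frame(chi2 = chi2, chi2_p = chi2_p,
                     mean_pa = mt$mean_pa, sd_pa = mt$sd_pa,
                     t = mt$t, t_df = mt$df, t_p = mt$p.value,
                     freq_sig_raw = isTRUE(chi2_p < alpha),
                     freq_sig_bonf = isTRUE(chi2_p < bonf),
                     mag_sig_raw = isTRUE(mt$p.value < alpha),
                     mag_sig_bonf = isTRUE(mt$p.value < bonf)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "n_tests") <- n_tests
  attr(out, "bonferroni_alpha") <- bonf
  out
}
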