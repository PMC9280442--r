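#' Fit a directional-asymmetry analysis
#'
#' The package's main entry point: takes per-specimen bilateral element
#' lengths, computes signed percent asymmetry, applies the outlier
#' screens, and tests every taxon x element sample for directional
#' asymmetry in two complementary ways — frequency (are left-larger and
#' right-larger individuals 50:50? [freq_asym_test()]) and magnitude (is
#' one side systematically larger? [magnitude_test()]) — with Bonferroni
#' correction across comparisons.
#'
#' The formula interface mirrors classical modelling functions:
#' `cbind(left, right) ~ taxon + element` names the two sides on the
#' left and the grouping factors on the right. The data-frame method
#' expects the canonical measurement columns (`taxon`, `specimen_id`,
#' `element`, `left_length`, `right_length`, and optionally `excluded`
#' and `exclusion_reason` carrying upstream exclusions such as broken
#' specimens).
#'
#' @param x a formula or a measurements data frame.
#' @param data for the formula method, the data frame holding the
#'   variables.
#' @param alpha raw per-test significance level.
#' @param n_tests Bonferroni family size per statistical approach
#'   (default: the number of taxon x element comparisons fitted).
#' @param filter_lengths apply the 3-SD length screen
#'   ([flag_length_outliers()]) before analysis (default `TRUE`).
#' @param filter_asymmetry additionally apply the post hoc 3-SD screen on
#'   percent-asymmetry values ([flag_asymmetry_outliers()]); off by
#'   default, as in the primary analysis convention.
#' @param t_on run the paired magnitude test on raw `"lengths"` (default)
#'   or on per-individual `"pa"` values.
#' @param ... passed between methods.
#' @return An object of class `dasym`: a list with `summary` (one row
#'   per comparison, see [summarize_asymmetry()]), `records` (the
#'   per-specimen asymmetry table after filtering), `exclusions` (every
#'   excluded record with its reason), `alpha`, `n_tests`,
#'   `bonferroni_alpha` and `call`. Methods: [print.dasym()],
#'   [summary.dasym()], [coef.dasym()], [residuals.dasym()],
#'   [plot.dasym()], [simulate.dasym()].
#' @examples
#' m <- rbind(simulate_measurements(80, mu_pa = -2, sigma_pa = 2,
#'                                  taxon = "A", seed = 1),
#'            simulate_measurements(80, mu_pa = 0, sigma_pa = 2,
#'                                  taxon = "B", seed = 2))
#' fit <- dasym(cbind(left_length, right_length) ~ taxon + element,
#'              data = m)
#' fit
#' coef(fit)
#' @export
dasym <- function(x, ...) UseMethod("dasym")

#' @rdname dasym
#' @export
dasym.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data, na.action = stats::na.pass)
  lhs <- mf[[1L]]
  .check(is.matrix(lhs) && ncol(lhs) == 2L,
         "left-hand side must be cbind(left, right)")
  groups <- mf[-1L]
  taxon <- if (length(groups) >= 1L) as.character(groups[[1L]]) else "all"
  element <- if (length(groups) >= 2L) as.character(groups[[2L]])
             else "element"
  m <- data.frame(taxon = taxon,
                  specimen_id = if ("specimen_id" %in% names(data))
                    as.character(data$specimen_id)
                  else sprintf("spec_%d", seq_len(nrow(mf))),
                  element = element,
                  left_length = lhs[, 1L], right_length = lhs[, 2L],
                  excluded = if ("excluded" %in% names(data))
                    data$excluded else FALSE,
                  exclusion_reason = if ("exclusion_reason" %in% names(data))
                    data$exclusion_reason else "none",
                  stringsAsFactors = FALSE)
  out <- dasym.data.frame(m, ...)
  out$call <- match.call()
  out
}

#' @rdname dasym
#' @export
dasym.data.frame <- function(x, alpha = 0.05, n_tests = NULL,
                             filter_lengths = TRUE,
                             filter_asymmetry = FALSE,
                             t_on = c("lengths", "pa"), ...) {
  t_on <- match.arg(t_on)
  m <- x
  if (!"excluded" %in% names(m)) m$excluded <- FALSE
  if (!"exclusion_reason" %in% names(m)) m$exclusion_reason <- "none"
  # records with a missing side can never yield asymmetry
  miss <- !m$excluded & (is.na(m$left_length) | is.na(m$right_length))
  m$excluded[miss] <- TRUE
  m$exclusion_reason[miss] <- "missing_side"
  .check_measurements(m)
  if (filter_lengths) m <- flag_length_outliers(m)
  rec <- asymmetry_records(m)
  if (filter_asymmetry) rec <- flag_asymmetry_outliers(rec)
  summ <- summarize_asymmetry(rec, alpha = alpha, n_tests = n_tests,
                              t_on = t_on)
  structure(list(
    summary = summ,
    records = rec,
    exclusions = rec[rec$excluded,
                     c("taxon", "specimen_id", "element",
                       "exclusion_reason")],
    alpha = alpha,
    n_tests = attr(summ, "n_tests"),
    bonferroni_alpha = attr(summ, "bonferroni_alpha"),
    t_on = t_on,
    call = match.call()),
    class = "dasym")
}

#' @export
print.dasym <- function(x, ...) {
  s <- x$summary
  cat("Directional asymmetry analysis:",
      nrow(s), "taxon x element comparison(s)\n")
  cat(sprintf("alpha = %.3g; Bonferroni-corrected alpha = %.3g (%d tests)\n\n",
              x$alpha, x$bonferroni_alpha, x$n_tests))
  tab <- data.frame(
    taxon = s$taxon, element = s$element, N = s$n,
    N_left = s$n_left_larger, N_right = s$n_right_larger,
    `chi2; p` = sprintf("%.2f; %s", s$chi2, format_p(s$chi2_p)),
    `mean PA (SD)` = sprintf("%.2f (%.2f)", s$mean_pa, s$sd_pa),
    `t; p` = ifelse(is.na(s$t), "NA",
                    sprintf("%.2f; %s", s$t, format_p(s$t_p))),
    sig = paste0(ifelse(s$freq_sig_raw, "F", ""),
                 ifelse(s$mag_sig_raw, "M", ""),
                 ifelse(s$freq_sig_bonf | s$mag_sig_bonf, "*", "")),
    check.names = FALSE)
  print(tab, row.names = FALSE, right = FALSE)
  cat("\nsig: F = frequency, M = magnitude significant at raw alpha;",
      "* survives Bonferroni\n")
  cat("Negative mean PA = left side larger.",
      if (nrow(x$exclusions))
        sprintf(" %d record(s) excluded.", nrow(x$exclusions)), "\n")
  invisible(x)
}

#' Detailed summary of a directional-asymmetry fit
#'
#' @param object a `dasym` fit.
#' @param ... unused.
#' @return The fit's per-comparison `summary` data frame (full numeric
#'   precision, with significance flags), printed together with the
#'   exclusion report.
#' @export
summary.dasym <- function(object, ...) {
  structure(list(summary = object$summary,
                 exclusions = object$exclusions,
                 alpha = object$alpha,
                 bonferroni_alpha = object$bonferroni_alpha),
            class = "summary.dasym")
}

#' @export
print.summary.dasym <- function(x, ...) {
  print(x$summary, digits = 4)
  cat(sprintf("\nBonferroni-corrected alpha: %.4g (raw %.3g)\n",
              x$bonferroni_alpha, x$alpha))
  if (nrow(x$exclusions)) {
    cat("\nExcluded records:\n")
    print(x$exclusions, row.names = FALSE)
  } else cat("\nNo records excluded.\n")
  invisible(x)
}

#' @export
coef.dasym <- function(object, ...) {
  s <- object$summary
  stats::setNames(s$mean_pa, paste(s$taxon, s$element, sep = ":"))
}

#' Fluctuating-asymmetry residuals
#'
#' @param object a `dasym` fit.
#' @param ... unused.
#' @return Per-specimen percent asymmetry minus the fitted group mean —
#'   the individual (fluctuating) component once the directional signal
#'   is removed. `NA` for excluded records.
#' @export
residuals.dasym <- function(object, ...) {
  r <- object$records
  key <- paste(r$taxon, r$element)
  s <- object$summary
  mu <- stats::setNames(s$mean_pa, paste(s$taxon, s$element))
  r$percent_asymmetry - mu[key]
}

#' Simulate datasets from a directional-asymmetry fit
#'
#' Parametric resampling: for each fitted taxon x element comparison,
#' generates new bilateral measurements via [simulate_measurements()] at
#' the fitted mean and SD of percent asymmetry, the observed sample size,
#' and the observed size distribution (median and log-scale SD of the
#' per-specimen midpoint lengths).
#'
#' @param object a `dasym` fit.
#' @param nsim number of simulated datasets.
#' @param seed integer seed; dataset s of group g uses a seed derived
#'   from `seed`, `s` and `g`.
#' @param ... unused.
#' @return A list of `nsim` measurements data frames.
#' @export
simulate.dasym <- function(object, nsim = 1, seed = 1, ...) {
  s <- object$summary
  r <- object$records[!object$records$excluded, ]
  lapply(seq_len(nsim), function(k) {
    sims <- lapply(seq_len(nrow(s)), function(g) {
      gi <- r[r$taxon == s$taxon[g] & r$element == s$element[g], ]
      mid <- (gi$left_length + gi$right_length) / 2
      simulate_measurements(
        n = s$n[g],
        mean_size = stats::median(mid),
        size_cv = stats::sd(log(mid[mid > 0])),
        mu_pa = s$mean_pa[g],
        sigma_pa = if (is.na(s$sd_pa[g])) 0 else s$sd_pa[g],
        taxon = s$taxon[g], element = s$element[g],
        seed = (seed + 7919L * k + 104729L * g) %% .Machine$integer.max)
    })
    do.call(rbind, sims)
  })
}

#' Rank-magnitude plot of a directional-asymmetry fit
#'
#' One panel per taxon x element comparison: each bar is an individual,
#' bar height its absolute percent asymmetry. Left-larger individuals
#' are drawn to the left of the vertical midline (their negative values
#' reflected upward), right-larger individuals to the right, each class
#' ranked by magnitude. The class percentages are annotated; they need
#' not sum to 100% because exactly symmetric individuals carry no bar.
#'
#' @param x a `dasym` fit.
#' @param which integer or logical index selecting comparisons (default
#'   all).
#' @param col two colours for the left- and right-larger classes.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the [rank_magnitude_data()] list used.
#' @export
plot.dasym <- function(x, which = NULL,
                       col = c("steelblue4", "tan3"), ...) {
  s <- x$summary
  idx <- seq_len(nrow(s))
  if (!is.null(which)) idx <- idx[which]
  if (length(idx) > 1L) {
    old <- graphics::par(mfrow = grDevices::n2mfrow(length(idx)))
    on.exit(graphics::par(old))
  }
  rmd <- lapply(idx, function(i) {
    d <- rank_magnitude_data(x$records, s$taxon[i], s$element[i])
    h <- c(rev(d$left_magnitudes), NA, d$right_magnitudes)
    graphics::barplot(h, border = NA, space = 0,
                      col = c(rep(col[1L], length(d$left_magnitudes)),
                              NA,
                              rep(col[2L], length(d$right_magnitudes))),
                      ylab = "|percent asymmetry|",
                      main = paste(s$taxon[i], s$element[i]), ...)
    graphics::abline(v = length(d$left_magnitudes) + 0.5, lty = 2)
    graphics::mtext(sprintf("left-larger %.0f%%   right-larger %.0f%%",
                            d$pct_left, d$pct_right),
                    side = 3, line = 0, cex = 0.8)
    d
  })
  invisible(rmd)
}
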