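#' Signed percent asymmetry
#'
#' The package's central per-specimen statistic:
#' \deqn{PA = 100 (R - L) / (R + L)}
#' where \eqn{L} and \eqn{R} are the left and right element lengths in
#' mm. A negative value means the left side is larger. The result is
#' rounded to two decimal places; individuals whose PA rounds to exactly
#' 0.00 are classed symmetric. PA is scale-free (invariant under
#' \eqn{L, R \to kL, kR}), which is what justifies pooling specimens of
#' different body size under an isometry assumption.
#'
#' @param left,right element lengths in mm (vectorized).
#' @return Signed percent asymmetry, rounded to 2 decimal places, in
#'   \[-100, 100\].
#' @examples
#' percent_asymmetry(2, 1)    # -33.33: left larger
#' percent_asymmetry(10, 10)  # 0
#' @export
percent_asymmetry <- function(left, right) {
  .check(all(is.finite(left)) && all(is.finite(right)),
         "lengths must be finite")
  .check(all(left >= 0) && all(right >= 0), "lengths must be non-negative")
  .check(all(left + right > 0),
         "percent asymmetry is undefined when left + right = 0")
  round2(100 * (right - left) / (right + left))
}

#' Classify asymmetry direction
#'
#' @param pa percent asymmetry already rounded to 2 decimal places.
#' @return Factor with levels `left_larger`, `right_larger`, `symmetric`:
#'   negative PA is `left_larger`, positive `right_larger`, exactly 0.00
#'   `symmetric`. `NA` PA stays `NA`.
#' @export
classify_direction <- function(pa) {
  out <- ifelse(is.na(pa), NA_character_,
         ifelse(pa < 0, "left_larger",
         ifelse(pa > 0, "right_larger", "symmetric")))
  factor(out, levels = c("left_larger", "right_larger", "symmetric"))
}

#' Attach percent asymmetry and direction to measurements
#'
#' @param measurements a measurements data frame (see
#'   [measure_specimen()] or [simulate_measurements()]).
#' @return The same table with columns `percent_asymmetry` and
#'   `direction` added; both are `NA` for excluded records or records
#'   with a missing side.
#' @export
asymmetry_records <- function(measurements) {
  .check_measurements(measurements)
  x <- measurements
  ok <- !x$excluded & !is.na(x$left_length) & !is.na(x$right_length)
  x$percent_asymmetry <- NA_real_
  x$percent_asymmetry[ok] <-
    percent_asymmetry(x$left_length[ok], x$right_length[ok])
  x$direction <- classify_direction(x$percent_asymmetry)
  x
}

## Shared single-pass 3-SD screen. values/groups are parallel vectors over
## candidate records; returns the logical flag vector. Mean and SD (n-1
## denominator) come from all candidate values in the group, computed once
## before any flagging -- the rule is deliberately NOT iterated within a
## call, so flagged values never shrink the SD that judges the others.
.flag_3sd <- function(values, groups, min_n = 3L) {
  flag <- rep(FALSE, length(values))
  for (g in unique(groups)) {
    i <- which(groups == g & !is.na(values))
    if (length(i) < min_n) next
    m <- mean(values[i]); s <- stats::sd(values[i])
    if (!is.finite(s) || s == 0) next  # zero variance: nothing can deviate
    flag[i] <- abs(values[i] - m) > 3 * s  # strict: exactly 3 SD stays
  }
  flag
}

#' Flag length outliers (3-SD screen on trait values)
#'
#' Quality screen applied before asymmetry is computed: within each
#' taxon x element x *side* group, a length more than 3 standard
#' deviations from the group mean (sample SD, n-1 denominator) flags the
#' whole bilateral record as excluded with reason `outlier_length`. Sides
#' are screened separately because directional asymmetry would inflate a
#' pooled SD. The screen is single-pass: the mean and SD are estimated
#' once from all non-excluded values and never re-estimated after
#' flagging. The whole record (both sides) is excluded because asymmetry
#' needs both sides; the same specimen's other element is untouched.
#' Groups with fewer than 3 usable values are left unscreened. In
#' practice flagged records should be checked against the original
#' digitization (misplaced landmarks are the usual cause) and can be
#' un-excluded by clearing the flag before analysis.
#'
#' @param measurements a measurements data frame.
#' @return The table with outlying records marked
#'   `excluded = TRUE, exclusion_reason = "outlier_length"`.
#' @export
flag_length_outliers <- function(measurements) {
  .check_measurements(measurements)
  x <- measurements
  cand <- !x$excluded
  grp <- paste(x$taxon, x$element, sep = "\r")
  flag <- rep(FALSE, nrow(x))
  for (side in c("left_length", "right_length"))
    flag <- flag | .flag_3sd(ifelse(cand, x[[side]], NA), grp)
  flag <- flag & cand
  x$excluded[flag] <- TRUE
  x$exclusion_reason[flag] <- "outlier_length"
  x
}

#' Flag percent-asymmetry outliers (post hoc 3-SD screen on PA)
#'
#' Optional second screen, off by default in [dasym()]: within each
#' taxon x element group, a percent-asymmetry value more than 3 standard
#' deviations from the group mean PA flags the record with reason
#' `outlier_asymmetry`. Same single-pass, strict-inequality, n-1-SD
#' conventions as [flag_length_outliers()]. On well-behaved data the
#' screen removes little and test decisions are unchanged; it exists to
#' catch digitization errors that survive the length screen because both
#' sides are plausible individually.
#'
#' @param records output of [asymmetry_records()].
#' @return The table with outlying records excluded and their
#'   `percent_asymmetry`/`direction` set to `NA`.
#' @export
flag_asymmetry_outliers <- function(records) {
  .check_measurements(records)
  .check("percent_asymmetry" %in% names(records),
         "run asymmetry_records() first")
  x <- records
  grp <- paste(x$taxon, x$element, sep = "\r")
  flag <- .flag_3sd(ifelse(!x$excluded, x$percent_asymmetry, NA), grp)
  flag <- flag & !x$excluded
  x$excluded[flag] <- TRUE
  x$exclusion_reason[flag] <- "outlier_asymmetry"
  x$percent_asymmetry[flag] <- NA_real_
  x$direction[flag] <- NA
  x
}

#' Per-sample direction counts
#'
#' Counts for one taxon x element sample, the unit of inference: total
#' usable specimens N and how many are left-larger, right-larger or
#' exactly symmetric (PA = 0.00 at 2 decimals). N can exceed
#' `n_left + n_right` because symmetric individuals count toward N but
#' carry no direction.
#'
#' @param records output of [asymmetry_records()] (any number of groups).
#' @return Data frame with one row per taxon x element: `taxon`,
#'   `element`, `n`, `n_left_larger`, `n_right_larger`, `n_symmetric`.
#' @export
asymmetry_counts <- function(records) {
  .check("direction" %in% names(records), "run asymmetry_records() first")
  x <- records[!records$excluded & !is.na(records$percent_asymmetry), ,
               drop = FALSE]
  groups <- unique(x[c("taxon", "element")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- x[x$taxon == groups$taxon[i] & x$element == groups$element[i], ]
    data.frame(taxon = groups$taxon[i], element = groups$element[i],
               n = nrow(g),
               n_left_larger = sum(g$direction == "left_larger"),
               n_right_larger = sum(g$direction == "right_larger"),
               n_symmetric = sum(g$direction == "symmetric"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(taxon = character(),
                                      element = character(), n = integer(),
                                      n_left_larger = integer(),
                                      n_right_larger = integer(),
                                      n_symmetric = integer())
  rownames(out) <- NULL
  out
}
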