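#' @keywords internal
"_PACKAGE"

## Valid vocabularies used across the package. Elements are deliberately an
## open set (config-driven), but sides and exclusion reasons are closed.
.sides <- c("left", "right")
.exclusion_reasons <- c("none", "broken", "outlier_length",
                        "outlier_asymmetry", "missing_side")

#' Round to two decimal places
#'
#' All lengths (mm) and percent-asymmetry values are rounded to two decimal
#' places once, at measurement time, and every downstream statistic consumes
#' the rounded values. Uses base [round()], which rounds half to even.
#'
#' @param x numeric vector.
#' @return `x` rounded to 2 decimal places.
#' @keywords internal
round2 <- function(x) round(x, 2L)

## Format a p-value the way comparative-morphology tables print them:
## three decimals with the leading zero stripped (".191"), "< .001" below
## the printable resolution. Reporting-layer only; full precision is kept
## in all returned objects.
format_p <- function(p) {
  out <- ifelse(is.na(p), "NA",
         ifelse(p < 0.0005, "< .001",
                sub("^(-?)0\\.", "\\1.", sprintf("%.3f", p))))
  out
}

## stopifnot() with a readable message
.check <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

## Validate a measurements data frame (the package's central flat table).
.check_measurements <- function(x) {
  need <- c("taxon", "specimen_id", "element",
            "left_length", "right_length", "excluded", "exclusion_reason")
  miss <- setdiff(need, names(x))
  .check(length(miss) == 0L,
         paste0("measurements table lacks column(s): ",
                paste(miss, collapse = ", ")))
  bad <- !x$excluded & x$exclusion_reason != "none"
  .check(!any(bad), "non-excluded records must have exclusion_reason 'none'")
  invisible(x)
}

## An empty measurements table with the canonical column set.
.empty_measurements <- function() {
  data.frame(taxon = character(), specimen_id = character(),
             element = character(),
             left_length = numeric(), right_length = numeric(),
             excluded = logical(), exclusion_reason = character(),
             stringsAsFactors = FALSE)
}
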