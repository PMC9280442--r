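#' Published asymmetry count summaries for limb-reduced squamates
#'
#' Per-taxon summary statistics from a published survey of directional
#' asymmetry in the vestigial pelves and femora of six limb-reduced
#' squamate taxa (amphisbaenians, a blind snake, and reduced-limbed
#' lizards): sample size, counts of left- and right-larger individuals,
#' the reported continuity-corrected chi-square and p, mean and SD of
#' signed percent asymmetry, and the reported paired t and p. These
#' count summaries are sufficient to re-run the frequency test (the
#' magnitude test needs the per-specimen lengths, which are not shipped);
#' they also provide realistic parameter regimes for
#' [simulate_measurements()].
#'
#' @return Data frame with columns `taxon`, `element`, `n`,
#'   `n_left_larger`, `n_right_larger`, `chi2`, `chi2_p`, `mean_pa`,
#'   `sd_pa`, `t`, `t_p`; one row per taxon x element comparison (9 rows).
#' @examples
#' vc <- vestige_counts()
#' freq_asym_test(vc$n_left_larger[1], vc$n_right_larger[1])
#' @export
vestige_counts <- function() {
  utils::read.csv(system.file("extdata", "squamate_vestige_counts.csv",
                              package = "dasym", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
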