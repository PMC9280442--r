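#' Rank-magnitude plot data for one comparison
#'
#' Computes the data behind a rank-magnitude asymmetry display: the
#' absolute percent-asymmetry values of the left-larger and right-larger
#' individuals of one taxon x element sample, each class sorted in
#' decreasing magnitude, plus each class's percentage of the usable
#' sample N. Percentages need not sum to 100 because exactly symmetric
#' individuals (PA = 0.00) belong to neither class. The result is
#' independent of input row order.
#'
#' @param records output of [asymmetry_records()] (or the `records` of a
#'   [dasym()] fit).
#' @param taxon,element select the sample; may be omitted when `records`
#'   contains a single taxon x element group.
#' @return A list of class `rank_magnitude`: `taxon`, `element`, `n`,
#'   `left_magnitudes`, `right_magnitudes` (sorted decreasing),
#'   `pct_left`, `pct_right`, `pct_symmetric`.
#' @examples
#' m <- simulate_measurements(50, mu_pa = -1, sigma_pa = 2, seed = 4)
#' rank_magnitude_data(asymmetry_records(m))
#' @export
rank_magnitude_data <- function(records, taxon = NULL, element = NULL) {
  .check("direction" %in% names(records), "run asymmetry_records() first")
  x <- records[!records$excluded & !is.na(records$percent_asymmetry), ]
  if (!is.null(taxon)) x <- x[x$taxon == taxon, ]
  if (!is.null(element)) x <- x[x$element == element, ]
  .check(nrow(x) > 0L, "no usable records in the selected sample")
  .check(nrow(unique(x[c("taxon", "element")])) == 1L,
         "records span several samples; select one with taxon=/element=")
  n <- nrow(x)
  left <- sort(abs(x$percent_asymmetry[x$direction == "left_larger"]),
               decreasing = TRUE)
  right <- sort(x$percent_asymmetry[x$direction == "right_larger"],
                decreasing = TRUE)
  structure(list(taxon = x$taxon[1L], element = x$element[1L], n = n,
                 left_magnitudes = left, right_magnitudes = right,
                 pct_left = 100 * length(left) / n,
                 pct_right = 100 * length(right) / n,
                 pct_symmetric = 100 * sum(x$direction == "symmetric") / n),
            class = "rank_magnitude")
}

#' @export
print.rank_magnitude <- function(x, ...) {
  cat(sprintf("Rank-magnitude data: %s %s (N = %d)\n", x$taxon, x$element,
              x$n),
      sprintf("  left-larger %.1f%%, right-larger %.1f%%, symmetric %.1f%%\n",
              x$pct_left, x$pct_right, x$pct_symmetric), sep = "")
  invisible(x)
}

## Long-format plot-data table across all comparisons (for CSV export)
.rank_magnitude_table <- function(records) {
  groups <- unique(records[!records$excluded, c("taxon", "element")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    d <- rank_magnitude_data(records, groups$taxon[i], groups$element[i])
    k <- c(length(d$left_magnitudes), length(d$right_magnitudes))
    if (sum(k) == 0L) return(NULL)
    data.frame(taxon = d$taxon, element = d$element,
               side = rep(c("left_larger", "right_larger"), k),
               rank = c(seq_len(k[1L]), seq_len(k[2L])),
               abs_pa = c(d$left_magnitudes, d$right_magnitudes),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(taxon = character(), element = character(),
                      side = character(), rank = integer(),
                      abs_pa = numeric())
  out
}

#' Run the full asymmetry pipeline and write its artifacts
#'
#' End-to-end orchestration: reads measurements (either a directory of
#' `.pp` landmark files plus a metadata sidecar, or a measurements CSV),
#' fits [dasym()], and writes every analysis artifact to `out_dir`:
#'
#' * `measurements.csv` — raw bilateral lengths per specimen x element;
#' * `asymmetry.csv` — with percent asymmetry and direction;
#' * `exclusions.csv` — every excluded record and its reason;
#' * `summary.csv` — one row per taxon x element comparison (counts,
#'   chi-square, mean/SD PA, paired t, significance flags);
#' * `plot_data.csv` — rank-magnitude display data;
#' * `pipeline_log.txt` — a machine-parseable log of every exclusion
#'   decision (`tab`-separated `specimen_id`, `element`, `reason`).
#'
#' The run is deterministic given its inputs.
#'
#' @param input a directory containing `.pp` files, or the path of a
#'   measurements CSV (columns as in [measure_specimen()]).
#' @param out_dir output directory, created if needed.
#' @param rules [landmark_rules()] used for `.pp` input.
#' @param metadata optional path of a specimen metadata CSV
#'   (`specimen_id`, `taxon`, optional `broken`) for `.pp` input.
#' @param ... options passed to [dasym()] (`alpha`, `filter_asymmetry`,
#'   `t_on`, ...).
#' @return The [dasym()] fit, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(input, out_dir,
                         rules = default_landmark_rules(),
                         metadata = NULL, ...) {
  .check(length(input) == 1L && file.exists(input),
         paste0("input '", input, "' does not exist"))
  if (dir.exists(input)) {
    meta <- if (!is.null(metadata))
      utils::read.csv(metadata, stringsAsFactors = FALSE) else NULL
    measurements <- measure_pp_dir(input, rules = rules, metadata = meta)
  } else {
    measurements <- utils::read.csv(input, stringsAsFactors = FALSE)
    .check_measurements(measurements)
  }
  fit <- dasym(measurements, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f)
    utils::write.csv(x, file.path(out_dir, f), row.names = FALSE)
  wr(measurements, "measurements.csv")
  wr(fit$records, "asymmetry.csv")
  wr(fit$exclusions, "exclusions.csv")
  s <- fit$summary
  s$bonferroni_alpha <- fit$bonferroni_alpha
  wr(s, "summary.csv")
  wr(.rank_magnitude_table(fit$records), "plot_data.csv")
  log_lines <- c("event\tspecimen_id\telement\treason",
                 sprintf("exclude\t%s\t%s\t%s",
                         fit$exclusions$specimen_id,
                         fit$exclusions$element,
                         fit$exclusions$exclusion_reason))
  writeLines(log_lines, file.path(out_dir, "pipeline_log.txt"))
  invisible(fit)
}
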