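# Fixtures are built in code; nothing binary ships with the tests.

# A minimal picked-points document built by string templating, so parser
# tests do not depend on write_pp().
pp_doc <- function(points = character(), extra = "") {
  paste(c("<!DOCTYPE PickedPoints>",
          "<PickedPoints>",
          " <DocumentData>",
          '  <DataFileName name="mesh.ply"/>',
          "  <templateName name=\"\"/>",
          " </DocumentData>",
          extra,
          points,
          "</PickedPoints>"), collapse = "\n")
}

pp_point <- function(name, x, y, z, active = 1, extra_attr = "") {
  sprintf(' <point x="%g" y="%g" z="%g" active="%d" name="%s" %s/>',
          x, y, z, active, name, extra_attr)
}

# Two specimens' worth of pelvis landmarks with known 3-4-5 geometry:
# every side has length exactly 5.
pelvis_landmarks <- function() {
  data.frame(
    name = c("pelvis_L_ant", "pelvis_L_post", "pelvis_R_ant",
             "pelvis_R_post"),
    x = c(0, 3, 10, 13), y = c(0, 4, 0, 4), z = 0,
    active = TRUE, stringsAsFactors = FALSE)
}

# Random landmark frame for round-trip property tests
random_landmarks <- function(n) {
  data.frame(
    name = paste0("lm_", sample(1e6, n)),
    x = stats::rnorm(n, 0, 100), y = stats::rnorm(n, 0, 100),
    z = stats::rnorm(n, 0, 100),
    active = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# Hand-rolled measurements table for filter/inference tests
make_measurements <- function(left, right, taxon = "T", element = "pelvis",
                              excluded = FALSE, reason = "none") {
  n <- length(left)
  data.frame(taxon = taxon,
             specimen_id = sprintf("s%03d", seq_len(n)),
             element = element,
             left_length = left, right_length = right,
             excluded = rep_len(excluded, n),
             exclusion_reason = rep_len(reason, n),
             stringsAsFactors = FALSE)
}

# The nine published taxon x element count pairs with their reported
# chi-square statistics and p-values (frozen golden values).
golden_counts <- function() {
  data.frame(
    n_left  = c(48, 38, 50, 44, 39, 23, 22, 44, 39),
    n_right = c(70, 57, 39, 47, 41, 51, 44, 27, 29),
    chi2    = c(1.71, 1.54, 0.46, 0.01, 0.00, 4.74, 3.12, 1.61, 0.47),
    p       = c(0.191, 0.215, 0.499, 0.941, 1.000, 0.030,
                0.077, 0.205, 0.492))
}

# Independent oracle for the frequency statistic: build the literal 2x2
# table and hand base R's chisq.test the Yates correction. Never calls
# package code.
oracle_freq_chi2 <- function(n_left, n_right) {
  E <- (n_left + n_right) / 2
  suppressWarnings(
    unname(stats::chisq.test(rbind(c(n_left, n_right), c(E, E)),
                             correct = TRUE)$statistic))
}

# Brute-force four-cell sum over the same table, written out cell by cell.
oracle_freq_chi2_bruteforce <- function(n_left, n_right) {
  obs <- rbind(c(n_left, n_right), c((n_left + n_right) / 2,
                                     (n_left + n_right) / 2))
  tot <- sum(obs)
  acc <- 0
  for (i in 1:2) for (j in 1:2) {
    e <- sum(obs[i, ]) * sum(obs[, j]) / tot
    dev <- max(abs(obs[i, j] - e) - 0.5, 0)
    acc <- acc + dev^2 / e
  }
  acc
}

# Monte-Carlo oracle for chi-square power at df = 1: the noncentral
# statistic is (Z + sqrt(lambda))^2.
oracle_power_mc <- function(w, n, alpha = 0.05, draws = 2e5) {
  lambda <- n * w^2
  crit <- stats::qchisq(1 - alpha, df = 1)
  x <- (stats::rnorm(draws) + sqrt(lambda))^2
  p <- mean(x > crit)
  list(power = p, se = sqrt(p * (1 - p) / draws))
}
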