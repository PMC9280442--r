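#' Simulate bilateral vestige measurements with known asymmetry
#'
#' Generates one taxon x element sample of left/right element lengths
#' with a known directional-asymmetry signal, for validating every stage
#' of the pipeline. Percent asymmetry — not the raw side difference — is
#' the generative primitive, so the true parameters live on the same
#' scale as the reported "mean PA (SD)" summaries. For specimen \eqn{i}:
#' \deqn{S_i = \mu_S e^{\epsilon_i},\ \epsilon_i \sim N(0, cv^2); \quad
#'       P_i \sim N(\mu_{PA}, \sigma_{PA}^2);}
#' \deqn{right_i = S_i (1 + P_i/100), \quad left_i = S_i (1 - P_i/100),}
#' so that `percent_asymmetry(left, right)` recovers \eqn{P_i} exactly
#' before rounding. The lognormal size model keeps lengths positive and,
#' because PA is scale-free, size variation never leaks into asymmetry —
#' the isometry assumption of the analysis, by construction. Here
#' \eqn{\sigma_{PA}} is the fluctuating-asymmetry noise: random
#' individual left-right deviation around the population bias
#' \eqn{\mu_{PA}} (negative = left-larger). With probability
#' `outlier_rate` a specimen gets one side multiplied by `outlier_scale`,
#' emulating gross digitization errors the 3-SD screens exist to catch.
#'
#' @param n number of specimens.
#' @param mean_size median element size \eqn{\mu_S} in mm.
#' @param size_cv among-specimen size variation (SD of log size,
#'   approximately the coefficient of variation).
#' @param mu_pa true mean signed percent asymmetry (%); must satisfy
#'   `abs(mu_pa) < 100`.
#' @param sigma_pa fluctuating-asymmetry SD of percent asymmetry (%).
#' @param outlier_rate per-specimen probability of a gross error.
#' @param outlier_scale multiplier applied to one random side of an
#'   outlier specimen.
#' @param taxon,element labels for the generated sample.
#' @param specimen_prefix prefix for generated specimen ids.
#' @param seed optional integer; when given, the RNG is seeded locally
#'   (the caller's RNG state is untouched) so equal parameters give
#'   identical samples.
#' @return A measurements data frame (see [measure_specimen()]) with two
#'   extra columns: `true_pa`, the generated pre-rounding percent
#'   asymmetry, and `is_outlier`, whether a gross error was injected.
#'   Lengths are rounded to 2 decimals like real measurements.
#' @examples
#' m <- simulate_measurements(10, mu_pa = -10, sigma_pa = 0, seed = 1)
#' asymmetry_records(m)$percent_asymmetry  # all -10
#' @export
simulate_measurements <- function(n, mean_size = 10, size_cv = 0.15,
                                  mu_pa = 0, sigma_pa = 1,
                                  outlier_rate = 0, outlier_scale = 3,
                                  taxon = "sim", element = "pelvis",
                                  specimen_prefix = taxon, seed = NULL) {
  .check(n >= 1, "need at least one specimen")
  .check(mean_size > 0, "mean_size must be positive")
  .check(size_cv >= 0 && sigma_pa >= 0, "dispersions must be non-negative")
  .check(abs(mu_pa) < 100, "mean PA must lie strictly inside (-100, 100)")
  .check(outlier_rate >= 0 && outlier_rate < 1,
         "outlier_rate must be in [0, 1)")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  size <- mean_size * exp(stats::rnorm(n, 0, size_cv))
  pa <- stats::rnorm(n, mu_pa, sigma_pa)
  right <- size * (1 + pa / 100)
  left <- size * (1 - pa / 100)
  is_out <- stats::runif(n) < outlier_rate
  out_side <- sample(.sides, n, replace = TRUE)
  left[is_out & out_side == "left"] <-
    left[is_out & out_side == "left"] * outlier_scale
  right[is_out & out_side == "right"] <-
    right[is_out & out_side == "right"] * outlier_scale
  data.frame(taxon = taxon,
             specimen_id = sprintf("%s_%0*d", specimen_prefix,
                                   nchar(as.character(n)), seq_len(n)),
             element = element,
             left_length = round2(left), right_length = round2(right),
             excluded = FALSE, exclusion_reason = "none",
             true_pa = pa, is_outlier = is_out,
             stringsAsFactors = FALSE)
}

## One uniformly random rotation matrix (QR of a Gaussian matrix, sign-fixed)
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Write simulated specimens as picked-points landmark files
#'
#' Renders a simulated measurements table as a directory of `.pp` files,
#' one per specimen, exercising the landmark pipeline end to end. Each
#' element side becomes two landmarks separated by exactly the stated
#' length, placed under a random rigid transform (rotation + translation)
#' per specimen, with optional isotropic Gaussian digitization noise of
#' SD `digit_noise` mm added independently to every landmark coordinate.
#' Landmark names follow the [default_landmark_rules()] scheme
#' (`pelvis_L_ant` ... `femur_R_dist`), so
#' `measure_pp_dir(dir)` inverts the process: at `digit_noise = 0`
#' recovered lengths equal the inputs exactly at 2 decimals.
#'
#' @param measurements a measurements data frame (typically from
#'   [simulate_measurements()]; multiple elements per specimen are
#'   supported via shared `specimen_id`s).
#' @param dir output directory (created if needed).
#' @param digit_noise per-coordinate digitization noise SD in mm.
#' @param seed optional integer seed (local, as in
#'   [simulate_measurements()]); with equal inputs and seed the emitted
#'   files are byte-identical.
#' @return Invisibly, the vector of file paths written.
#' @export
simulate_landmark_files <- function(measurements, dir, digit_noise = 0,
                                    seed = NULL) {
  .check_measurements(measurements)
  .check(digit_noise >= 0, "digit_noise must be non-negative")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  role_suffix <- function(el) if (el == "femur") c("prox", "dist")
                              else c("ant", "post")
  ids <- unique(measurements$specimen_id)
  paths <- character(0)
  for (id in ids) {
    rows <- measurements[measurements$specimen_id == id, , drop = FALSE]
    R <- .random_rotation()
    shift <- stats::rnorm(3, 0, 50)
    pts <- list()
    for (r in seq_len(nrow(rows))) {
      el <- rows$element[r]
      for (s in .sides) {
        len <- rows[[paste0(s, "_length")]][r]
        if (is.na(len)) next
        # local frame: the element lies along x; sides offset along y
        y0 <- if (s == "left") -5 else 5
        local <- rbind(c(0, y0, 0), c(len, y0, 0))
        world <- t(R %*% t(local)) + rep(shift, each = 2)
        if (digit_noise > 0)
          world <- world + matrix(stats::rnorm(6, 0, digit_noise), 2)
        suf <- role_suffix(el)
        pts[[length(pts) + 1L]] <- data.frame(
          name = sprintf("%s_%s_%s", el,
                         if (s == "left") "L" else "R", suf),
          x = world[, 1], y = world[, 2], z = world[, 3],
          active = TRUE, stringsAsFactors = FALSE)
      }
    }
    .check(length(pts) > 0L,
           paste0("specimen '", id, "' has no measurable side to write"))
    path <- file.path(dir, paste0(id, ".pp"))
    write_pp(do.call(rbind, pts), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Monte-Carlo validation of the inference pipeline
#'
#' Repeatedly simulates a sample at known parameters, runs the asymmetry
#' summary (optionally including the outlier screens), and reports
#' empirical rejection rates of both tests plus the bias of the mean-PA
#' estimate, each with its Monte-Carlo standard error. Under the null
#' (`mu_pa = 0`) the frequency test should reject clearly below alpha
#' (the continuity correction is conservative) and the t-test at about
#' alpha; under a real signal the rejection rates are empirical power.
#'
#' @param n_replicates number of simulated samples (>= 100 for usable
#'   Monte-Carlo error).
#' @param alpha rejection threshold for both tests.
#' @param filter logical: apply [flag_length_outliers()] before testing.
#' @param seed integer; replicate r uses local seed `seed + r`.
#' @param ... sample parameters passed to [simulate_measurements()]
#'   (`n`, `mu_pa`, `sigma_pa`, ...).
#' @return A list of class `recovery_experiment`: `freq_reject_rate`,
#'   `t_reject_rate` (with `*_se`), `mean_pa_bias` (mean estimated minus
#'   true mean PA, with `mean_pa_bias_se`), and `n_replicates`.
#' @export
recovery_experiment <- function(n_replicates = 200, alpha = 0.05,
                                filter = FALSE, seed = 1, ...) {
  .check(n_replicates >= 100, "need at least 100 replicates")
  args <- list(...)
  mu_pa <- if (is.null(args$mu_pa)) 0 else args$mu_pa
  freq_rej <- t_rej <- logical(n_replicates)
  est <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    m <- do.call(simulate_measurements, c(args, list(seed = seed + r)))
    if (filter) m <- flag_length_outliers(m)
    rec <- asymmetry_records(m)
    cnt <- asymmetry_counts(rec)
    freq_rej[r] <- if (nrow(cnt) == 1L &&
                       cnt$n_left_larger + cnt$n_right_larger >= 1) {
      freq_asym_test(cnt$n_left_larger, cnt$n_right_larger)$p.value < alpha
    } else FALSE
    ok <- rec[!rec$excluded, ]
    mt <- magnitude_test(ok$left_length, ok$right_length)
    t_rej[r] <- !is.na(mt$p.value) && mt$p.value < alpha
    est[r] <- mt$mean_pa
  }
  rate_se <- function(p) sqrt(p * (1 - p) / n_replicates)
  structure(list(
    freq_reject_rate = mean(freq_rej),
    freq_reject_se = rate_se(mean(freq_rej)),
    t_reject_rate = mean(t_rej),
    t_reject_se = rate_se(mean(t_rej)),
    mean_pa_bias = mean(est) - mu_pa,
    mean_pa_bias_se = stats::sd(est) / sqrt(n_replicates),
    n_replicates = n_replicates, alpha = alpha),
    class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat("Pipeline recovery experiment (", x$n_replicates, " replicates, ",
      "alpha = ", x$alpha, ")\n",
      sprintf("  frequency-test rejection rate: %.3f (MC SE %.3f)\n",
              x$freq_reject_rate, x$freq_reject_se),
      sprintf("  paired-t rejection rate:       %.3f (MC SE %.3f)\n",
              x$t_reject_rate, x$t_reject_se),
      sprintf("  mean-PA bias:                  %+.4f%% (MC SE %.4f)\n",
              x$mean_pa_bias, x$mean_pa_bias_se), sep = "")
  invisible(x)
}
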