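make_two_taxon_data <- function() {
  rbind(simulate_measurements(80, mu_pa = -2, sigma_pa = 2, taxon = "A",
                              seed = 51),
        simulate_measurements(70, mu_pa = 0, sigma_pa = 2, taxon = "B",
                              seed = 52))
}

test_that("formula and data-frame interfaces agree", {
  m <- make_two_taxon_data()
  f1 <- dasym(cbind(left_length, right_length) ~ taxon + element,
              data = m)
  f2 <- dasym(m)
  expect_equal(f1$summary, f2$summary, ignore_attr = TRUE)
  expect_s3_class(f1, "dasym")
  expect_equal(f1$bonferroni_alpha, 0.05 / nrow(f1$summary))
})

test_that("the fit detects the planted signal and not the null", {
  fit <- dasym(make_two_taxon_data())
  s <- fit$summary
  a <- s[s$taxon == "A", ]; b <- s[s$taxon == "B", ]
  expect_true(a$mag_sig_raw)
  expect_lt(a$mean_pa, 0)
  expect_lt(a$t, 0)
  expect_false(b$mag_sig_raw && b$freq_sig_raw)
})

test_that("records with a missing side are excluded up front", {
  m <- make_measurements(c(5, 5, NA), c(5.2, NA, 5))
  fit <- dasym(m, filter_lengths = FALSE)
  expect_equal(fit$summary$n, 1)
  expect_equal(sort(fit$exclusions$specimen_id), c("s002", "s003"))
  expect_true(all(fit$exclusions$exclusion_reason == "missing_side"))
})

test_that("filter switches control the outlier screens", {
  m <- make_two_taxon_data()
  m$right_length[1] <- 60  # gross digitization error
  raw <- dasym(m, filter_lengths = FALSE)
  scr <- dasym(m)
  expect_equal(nrow(raw$exclusions), 0)
  expect_true("outlier_length" %in% scr$exclusions$exclusion_reason)
  both <- dasym(m, filter_asymmetry = TRUE)
  expect_gte(nrow(both$exclusions), nrow(scr$exclusions))
})

test_that("coef, residuals and summary expose the fit", {
  fit <- dasym(make_two_taxon_data())
  cf <- coef(fit)
  expect_named(cf, c("A:pelvis", "B:pelvis"))
  expect_equal(unname(cf), fit$summary$mean_pa)
  res <- residuals(fit)
  expect_length(res, nrow(fit$records))
  for (tx in c("A", "B")) {
    i <- fit$records$taxon == tx & !fit$records$excluded
    expect_equal(mean(res[i]), 0, tolerance = 1e-10)
  }
  out <- capture.output(print(fit))
  expect_true(any(grepl("Bonferroni", out)))
  out2 <- capture.output(print(summary(fit)))
  expect_true(any(grepl("alpha", out2)))
})

test_that("simulate() regenerates datasets at the fitted regime", {
  fit <- dasym(make_two_taxon_data())
  sims <- simulate(fit, nsim = 2, seed = 53)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]], sims[[2]]))
  s1 <- sims[[1]]
  expect_equal(nrow(s1), sum(fit$summary$n))
  refit <- dasym(s1, filter_lengths = FALSE)
  expect_equal(refit$summary$mean_pa, fit$summary$mean_pa,
               tolerance = 1)  # within sampling noise at n = 70-80
})

test_that("plot() renders rank-magnitude panels silently", {
  fit <- dasym(make_two_taxon_data())
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  rmd <- plot(fit)
  expect_length(rmd, 2)
  expect_s3_class(rmd[[1]], "rank_magnitude")
})
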