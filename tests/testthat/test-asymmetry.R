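test_that("percent asymmetry follows the signed formula at 2 dp", {
  expect_identical(percent_asymmetry(10, 10), 0)
  expect_identical(percent_asymmetry(2, 1), -33.33)
  expect_identical(percent_asymmetry(1, 2), 33.33)
  expect_error(percent_asymmetry(0, 0), "undefined")
  expect_error(percent_asymmetry(-1, 2), "non-negative")
})

test_that("percent asymmetry is antisymmetric and scale-free", {
  set.seed(11)
  for (i in 1:50) {
    a <- runif(1, 0.5, 50); b <- runif(1, 0.5, 50); k <- runif(1, 0.1, 20)
    expect_identical(percent_asymmetry(a, b), -percent_asymmetry(b, a))
    expect_equal(percent_asymmetry(k * a, k * b),
                 percent_asymmetry(a, b), tolerance = 0.011)
    expect_true(abs(percent_asymmetry(a, b)) <= 100)
  }
})

test_that("direction classification keys on the sign of rounded PA", {
  expect_equal(as.character(classify_direction(c(-0.01, 0, 0.66, NA))),
               c("left_larger", "symmetric", "right_larger", NA))
})

test_that("asymmetry_records computes PA only for usable records", {
  m <- make_measurements(c(2, 5, 4), c(1, 5, 4.2))
  m$excluded[3] <- TRUE; m$exclusion_reason[3] <- "broken"
  r <- asymmetry_records(m)
  expect_equal(r$percent_asymmetry, c(-33.33, 0, NA))
  expect_equal(as.character(r$direction),
               c("left_larger", "symmetric", NA))
})

test_that("length outliers beyond 3 SD are flagged, single-pass", {
  # brute-force oracle: z-scores from the group's own mean/SD
  left <- c(rep(5, 99), 50)
  right <- rep(5, 100)
  m <- make_measurements(left, right)
  f <- flag_length_outliers(m)
  z <- abs(left - mean(left)) / sd(left)
  expect_identical(which(f$excluded), which(z > 3))
  expect_identical(which(f$excluded), 100L)
  expect_equal(f$exclusion_reason[100], "outlier_length")
})

test_that("zero-variance groups and exact 3-SD values are not flagged", {
  m <- make_measurements(rep(5, 10), rep(5, 10))
  expect_false(any(flag_length_outliers(m)$excluded))
  # values landing exactly at mean +/- 3 SD: the strict rule keeps them
  # (17 zeros plus one value at -3 and one at +3 give sd exactly 1)
  v <- c(rep(0, 17), -3, 3)
  z <- abs(v - mean(v)) / sd(v)
  expect_identical(max(z), 3)
  m2 <- make_measurements(v + 10, rep(10, 19))
  expect_false(any(flag_length_outliers(m2)$excluded))
})

test_that("sides are screened separately so direction cannot mask outliers", {
  # strong directional asymmetry: every left 10% larger; one gross right
  set.seed(3)
  left <- round(rnorm(60, 11, 0.1), 2)
  right <- round(rnorm(60, 10, 0.1), 2)
  right[60] <- 30
  f <- flag_length_outliers(make_measurements(left, right))
  expect_identical(which(f$excluded), 60L)
})

test_that("asymmetry outliers are flagged per taxon x element on PA", {
  left <- rep(10, 100)
  right <- c(rep(10, 99), 14)  # PA = 0 except one at +16.67
  r <- asymmetry_records(make_measurements(left, right))
  f <- flag_asymmetry_outliers(r)
  expect_identical(which(f$excluded), 100L)
  expect_equal(f$exclusion_reason[100], "outlier_asymmetry")
  expect_true(is.na(f$percent_asymmetry[100]))
  # symmetric, well-behaved PA: nothing flagged
  set.seed(5)
  m2 <- simulate_measurements(100, mu_pa = 0, sigma_pa = 1, seed = 5)
  r2 <- asymmetry_records(m2)
  f2 <- flag_asymmetry_outliers(r2)
  expect_true(all(abs(r2$percent_asymmetry -
                        mean(r2$percent_asymmetry)) <=
                    3 * sd(r2$percent_asymmetry) |
                    f2$excluded))
})

test_that("direction counts satisfy the sample identity after filtering", {
  set.seed(9)
  m <- simulate_measurements(200, mu_pa = -1, sigma_pa = 2,
                             outlier_rate = 0.05, outlier_scale = 4,
                             seed = 9)
  m <- flag_length_outliers(m)
  r <- flag_asymmetry_outliers(asymmetry_records(m))
  cnt <- asymmetry_counts(r)
  expect_equal(cnt$n_left_larger + cnt$n_right_larger + cnt$n_symmetric,
               cnt$n)
  expect_equal(cnt$n, sum(!r$excluded))
})
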