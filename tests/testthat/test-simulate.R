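test_that("the noiseless generator is exact", {
  m0 <- simulate_measurements(20, mu_pa = 0, sigma_pa = 0, size_cv = 0,
                              seed = 1)
  r0 <- asymmetry_records(m0)
  expect_true(all(r0$percent_asymmetry == 0))
  expect_true(all(r0$direction == "symmetric"))

  # with size_cv = 0 every length is an exact 2-dp value (11 and 9 mm),
  # so rounding cannot perturb the constructed PA
  m1 <- simulate_measurements(20, mu_pa = -10, sigma_pa = 0, size_cv = 0,
                              seed = 2)
  r1 <- asymmetry_records(m1)
  expect_true(all(r1$percent_asymmetry == -10))
  expect_true(all(r1$direction == "left_larger"))
})

test_that("empirical PA mean and SD converge to the parameters", {
  n <- 5000
  m <- simulate_measurements(n, mu_pa = -1, sigma_pa = 2, seed = 3)
  pa <- asymmetry_records(m)$percent_asymmetry
  expect_lt(abs(mean(pa) - (-1)), 3 * 2 / sqrt(n))
  expect_lt(abs(sd(pa) - 2), 3 * 2 / sqrt(2 * n) + 0.01)
})

test_that("all randomness flows from the seed", {
  a <- simulate_measurements(50, mu_pa = 1, outlier_rate = 0.1, seed = 7)
  b <- simulate_measurements(50, mu_pa = 1, outlier_rate = 0.1, seed = 7)
  expect_identical(a, b)
  c_ <- simulate_measurements(50, mu_pa = 1, outlier_rate = 0.1, seed = 8)
  expect_false(identical(a, c_))
  # seeding is local: the caller's RNG stream is untouched
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(simulate_measurements(5, seed = 9))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("injected outliers are caught by the length screen", {
  m <- simulate_measurements(300, mu_pa = 0, sigma_pa = 1,
                             outlier_rate = 0.03, outlier_scale = 5,
                             seed = 10)
  expect_gt(sum(m$is_outlier), 0)
  f <- flag_length_outliers(m)
  expect_true(all(f$excluded[m$is_outlier]))
})

test_that("zero-noise landmark files round-trip lengths exactly", {
  m <- rbind(simulate_measurements(15, taxon = "T", element = "pelvis",
                                   seed = 11),
             simulate_measurements(15, taxon = "T", element = "femur",
                                   seed = 12))
  d <- withr::local_tempdir()
  simulate_landmark_files(m, d, digit_noise = 0, seed = 13)
  got <- measure_pp_dir(d, metadata = data.frame(
    specimen_id = unique(m$specimen_id), taxon = "T"))
  key <- function(x) x[order(x$specimen_id, x$element), ]
  g <- key(got); e <- key(m)
  expect_identical(g$left_length, e$left_length)
  expect_identical(g$right_length, e$right_length)
})

test_that("same seed gives byte-identical landmark files", {
  m <- simulate_measurements(5, seed = 14)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_landmark_files(m, d1, digit_noise = 0.05, seed = 15)
  simulate_landmark_files(m, d2, digit_noise = 0.05, seed = 15)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("digitization noise propagates within the expected bound", {
  # each landmark gets iid N(0, 0.05) per coordinate; the induced length
  # error is far inside 0.3 mm for at least 99% of records
  m <- simulate_measurements(300, mean_size = 10, seed = 16)
  d <- withr::local_tempdir()
  simulate_landmark_files(m, d, digit_noise = 0.05, seed = 17)
  got <- measure_pp_dir(d)
  g <- got[order(got$specimen_id), ]
  e <- m[order(m$specimen_id), ]
  err <- abs(g$left_length - e$left_length)
  err <- c(err, abs(g$right_length - e$right_length))
  expect_gte(mean(err <= 0.3), 0.99)
})

test_that("the recovery experiment reports calibrated rates and bias", {
  null <- recovery_experiment(n_replicates = 120, n = 60, mu_pa = 0,
                              sigma_pa = 2, seed = 18)
  expect_lt(null$freq_reject_rate, 0.12)
  expect_lt(null$t_reject_rate, 0.15)
  expect_lt(abs(null$mean_pa_bias), 4 * null$mean_pa_bias_se + 0.05)
  sig <- recovery_experiment(n_replicates = 120, n = 80, mu_pa = -3,
                             sigma_pa = 1, seed = 19)
  expect_gt(sig$t_reject_rate, 0.95)
  expect_gt(sig$freq_reject_rate, 0.95)
  expect_error(recovery_experiment(n_replicates = 10), "100")
})

test_that("estimate bias shrinks as the sample grows", {
  bias <- sapply(c(50, 500, 5000), function(n) {
    m <- simulate_measurements(n, mu_pa = -1, sigma_pa = 2,
                               seed = 20 + n)
    abs(mean(asymmetry_records(m)$percent_asymmetry) + 1)
  })
  expect_lt(bias[3], 3 * 2 / sqrt(5000))
})
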