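test_that("the frequency test reproduces the nine published statistics", {
  g <- golden_counts()
  for (i in seq_len(nrow(g))) {
    ft <- freq_asym_test(g$n_left[i], g$n_right[i])
    expect_equal(round(unname(ft$statistic), 2), g$chi2[i])
    expect_equal(round(ft$p.value, 3), g$p[i])
  }
})

test_that("the uncorrected goodness-of-fit does not reproduce them", {
  gof <- freq_asym_test(48, 70, method = "gof")
  expect_equal(round(unname(gof$statistic), 2), 4.10)
  expect_false(round(unname(gof$statistic), 2) == 1.71)
})

test_that("the statistic matches independent oracles on random counts", {
  set.seed(101)
  for (i in 1:300) {
    nl <- sample(0:200, 1); nr <- sample(0:200, 1)
    if (nl + nr == 0) nr <- 1
    stat <- unname(freq_asym_test(nl, nr)$statistic)
    expect_equal(stat, oracle_freq_chi2_bruteforce(nl, nr))
    expect_equal(stat, oracle_freq_chi2(nl, nr))
    # swap invariance: depends only on the unordered pair
    expect_equal(stat, unname(freq_asym_test(nr, nl)$statistic))
  }
})

test_that("counts differing by at most one give a zero statistic", {
  # the cell deviation is |n_left - n_right|/4, so the 0.5 continuity
  # clamp zeroes the statistic for count differences up to 2 (hence the
  # published 0.00 for 39 vs 41)
  for (k in c(1, 2, 10, 57)) {
    expect_identical(unname(freq_asym_test(k, k)$statistic), 0)
    expect_identical(unname(freq_asym_test(k, k + 1)$statistic), 0)
    expect_equal(freq_asym_test(k, k)$p.value, 1)
  }
  expect_identical(unname(freq_asym_test(10, 12)$statistic), 0)
  expect_gt(unname(freq_asym_test(10, 13)$statistic), 0)
  expect_error(freq_asym_test(0, 0), "no informative")
})

test_that("the expected per-side count uses the symmetric-excluded total", {
  ft <- freq_asym_test(48, 70)
  expect_equal(ft$expected, 59)  # (48 + 70) / 2, not N/2 = 62
})

test_that("the exact binomial alternative matches binom.test", {
  expect_equal(freq_asym_test(23, 51, method = "binomial")$p.value,
               binom.test(23, 74, 0.5)$p.value)
})

test_that("the paired magnitude test matches hand-computed examples", {
  # differences (2, 0, 2, 0): mean 1, sd 2/sqrt(3), t = sqrt(3)
  mt <- magnitude_test(c(10, 10, 10, 10), c(12, 10, 12, 10))
  expect_equal(mt$t, sqrt(3), tolerance = 1e-12)
  expect_equal(round(mt$t, 3), 1.732)
  expect_equal(mt$df, 3L)
  expect_equal(mt$p.value, 2 * pt(sqrt(3), 3, lower.tail = FALSE))
  # differences (1, 3): t = 2, df = 1
  mt2 <- magnitude_test(c(5, 5), c(6, 8))
  expect_equal(mt2$t, 2, tolerance = 1e-12)
  expect_equal(mt2$df, 1L)
})

test_that("zero-variance differences give an undefined t", {
  mt <- magnitude_test(c(4, 5, 6), c(4, 5, 6))
  expect_true(is.na(mt$t))
  expect_true(is.na(mt$p.value))
  expect_equal(mt$df, 2L)
  expect_equal(mt$mean_pa, 0)
})

test_that("t sign follows mean percent asymmetry", {
  set.seed(21)
  for (mu in c(-3, -0.5, 0.5, 3)) {
    m <- simulate_measurements(40, mu_pa = mu, sigma_pa = 1,
                               seed = 100 + mu)
    mt <- magnitude_test(m$left_length, m$right_length)
    expect_equal(sign(mt$t), sign(mt$mean_pa))
    mt_pa <- magnitude_test(m$left_length, m$right_length, on = "pa")
    expect_equal(sign(mt_pa$t), sign(mt$mean_pa))
  }
})

test_that("Bonferroni threshold divides the family alpha", {
  expect_equal(round(bonferroni_alpha(9, 0.05), 3), 0.006)
  expect_equal(bonferroni_alpha(1, 0.05), 0.05)
  expect_equal(bonferroni_alpha(2, 0.10), 0.05)
  expect_error(bonferroni_alpha(0), "at least 1")
})

test_that("the summary table matches an independent per-group recount", {
  set.seed(31)
  m <- rbind(
    simulate_measurements(60, mu_pa = -1, sigma_pa = 2, taxon = "A",
                          element = "pelvis", seed = 31),
    simulate_measurements(50, mu_pa = 2, sigma_pa = 1, taxon = "B",
                          element = "femur", seed = 32))
  r <- asymmetry_records(m)
  s <- summarize_asymmetry(r, n_tests = 9)
  expect_equal(nrow(s), 2)
  for (i in 1:2) {
    g <- r[r$taxon == s$taxon[i] & !r$excluded, ]
    expect_equal(s$n[i], nrow(g))
    expect_equal(s$n_left_larger[i], sum(g$percent_asymmetry < 0))
    expect_equal(s$n_right_larger[i], sum(g$percent_asymmetry > 0))
    expect_equal(s$mean_pa[i], mean(g$percent_asymmetry))
    expect_equal(unname(s$chi2[i]),
                 oracle_freq_chi2(s$n_left_larger[i], s$n_right_larger[i]))
    tt <- t.test(g$right_length, g$left_length, paired = TRUE)
    expect_equal(s$t[i], unname(tt$statistic))
    expect_equal(s$t_df[i], nrow(g) - 1)
  }
  expect_equal(attr(s, "bonferroni_alpha"), 0.05 / 9)
})

test_that("a fully symmetric sample yields no frequency test and NA t", {
  m <- make_measurements(rep(5, 10), rep(5, 10))
  s <- summarize_asymmetry(asymmetry_records(m))
  expect_equal(s$n_symmetric, 10)
  expect_true(is.na(s$chi2))
  expect_true(is.na(s$t))
  expect_error(freq_asym_test(0, 0), "no informative")
})
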