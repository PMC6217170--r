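test_that("expected-event calibration averages the early samples", {
  expect_equal(calibrate_expected_events(c(10000, 10000, 10000)), 10000)
  expect_equal(calibrate_expected_events(c(9000, 10000, 11000)), 10000)
  expect_error(calibrate_expected_events(c(1, 2)), ">= 3")
  expect_error(calibrate_expected_events(c(NA, 1, 2)), "finite")
})

test_that("clog correction rescales the gated fraction", {
  expect_equal(absolute_count(6000, 8000, 10000), 7500)
  expect_equal(absolute_count(6000, 10000, 10000), 6000)  # no clogging
  expect_equal(absolute_count(0, 8000, 10000), 0)
  expect_error(absolute_count(0, 0, 10000), "clogged")
})

test_that("corrected counts are invariant to uniform subsampling in expectation", {
  set.seed(11)
  e_i <- 10000; c_true <- 2000
  # subsample events at random retention rates; the corrected count
  # should scatter around the truth irrespective of attenuation
  est <- vapply(1:200, function(i) {
    keep <- runif(1, 0.4, 1)
    e_total <- rbinom(1, e_i, keep)
    e_cells <- rbinom(1, e_total, c_true / e_i)
    absolute_count(e_cells, e_total, e_i)
  }, numeric(1))
  expect_lt(abs(mean(est) - c_true) / c_true, 0.02)
})

test_that("two-component mixture recovery at n = 10^4 seeded events", {
  set.seed(101)
  x <- c(rnorm(6000, 100, 15), rnorm(4000, 200, 15))
  fit <- fit_dna_mixture(x)
  expect_false(fit$degenerate)
  expect_lt(abs(fit$w2 - 0.40), 0.02)
  expect_lt(abs(fit$mu2 / fit$mu1 - 2), 0.05)
  expect_lt(abs(fit$mu1 - 100) / 100, 0.03)
  expect_lt(abs(fit$mu2 - 200) / 200, 0.03)
  expect_equal(fit$w1 + fit$w2, 1, tolerance = 1e-9)
})

test_that("mixture fit agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(202)
  x <- c(rnorm(5000, 100, 15), rnorm(5000, 200, 18))
  fit <- fit_dna_mixture(x)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  mu_mc <- sort(mc$parameters$mean)
  expect_equal(c(fit$mu1, fit$mu2), unname(mu_mc), tolerance = 0.01)
  w_mc <- mc$parameters$pro[order(mc$parameters$mean)]
  expect_equal(c(fit$w1, fit$w2), unname(w_mc), tolerance = 0.02)
})

test_that("single-population input collapses to one component, flagged", {
  set.seed(33)
  x <- rnorm(5000, 100, 15)
  fit <- fit_dna_mixture(x)
  expect_true(fit$degenerate)
  expect_gt(max(fit$w1, fit$w2), 0.98)
})

test_that("two point masses are split exactly", {
  x <- rep(c(100, 200), each = 500)
  fit <- fit_dna_mixture(x)
  expect_equal(c(fit$w1, fit$w2), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(c(fit$mu1, fit$mu2), c(100, 200), tolerance = 1e-6)
})

test_that("subpopulation counts conserve the corrected total", {
  set.seed(7)
  x <- c(rnorm(600, 100, 15), rnorm(400, 200, 15))
  mix <- fit_dna_mixture(x)
  n <- subpopulation_counts(1000, mix)
  expect_equal(sum(n), 1000)
  expect_equal(unname(n[1] / n[2]), mix$w1 / mix$w2, tolerance = 1e-12)
})

test_that("division bookkeeping predicts the 1N pool from the 2N drain", {
  # one division wave: n2 400 -> 100 deposits 600 new 1N cells
  res <- check_2n_to_1n(c(0, 60), n1 = c(600, 1200), n2 = c(400, 100))
  expect_equal(res$n1_pred, c(600, 1200))
  expect_equal(res$residuals, c(0, 0))
  expect_true(res$consistent)

  # no 2N change: prediction unchanged
  res0 <- check_2n_to_1n(c(0, 60), n1 = c(600, 600), n2 = c(400, 400))
  expect_equal(res0$n1_pred, c(600, 600))

  # growing 2N pool violates the drain-only hypothesis
  resg <- check_2n_to_1n(c(0, 60), n1 = c(600, 600), n2 = c(400, 600))
  expect_true(resg$n2_increase_flag)
  expect_false(resg$consistent)
})

test_that("closed loop: rule-generated series with 2% noise is consistent at 5%", {
  set.seed(55)
  tt <- seq(0, 300, by = 30)
  n2 <- 400 * exp(-0.01 * pmax(0, tt - 60))
  n1 <- 600 + 2 * (400 - n2)
  noisy1 <- n1 * (1 + rnorm(length(tt), 0, 0.02))
  noisy2 <- n2 * (1 + rnorm(length(tt), 0, 0.02))
  res <- check_2n_to_1n(tt, noisy1, noisy2, tolerance = 0.05)
  expect_true(res$consistent)
})
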