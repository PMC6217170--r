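test_that("outlier rule drops only points 3 sd above the mean", {
  # ten 0.3s plus one 1.0: mean 0.3636, sd 0.2110, cutoff 0.9968
  od <- c(rep(0.3, 10), 1.0)
  out <- exclude_outliers(seq_along(od), od)
  expect_equal(out$n_excluded, 1L)
  expect_false(1.0 %in% out$od)

  const <- exclude_outliers(1:5, rep(0.4, 5))
  expect_equal(const$n_excluded, 0L)

  ramp <- seq(0.3, 0.33, length.out = 20)
  expect_equal(exclude_outliers(seq_along(ramp), ramp)$n_excluded, 0L)
})

test_that("changepoint fit recovers noise-free piecewise data exactly", {
  s <- make_od_series(od_i = 0.30, t_lag = 200, mu = 5e-4)
  fit <- fit_threshold_linear(s$time, s$od)
  expect_false(fit$censored)
  expect_equal(fit$od_i, 0.30, tolerance = 1e-8)
  expect_equal(fit$mu, 5e-4, tolerance = 1e-6)
  expect_equal(fit$t_lag, 200, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-12)
})

test_that("flat series are censored, not assigned a lag", {
  s <- make_od_series(mu = 0, t_lag = 100)
  fit <- fit_threshold_linear(s$time, s$od)
  expect_true(fit$censored)
  expect_true(is.na(fit$t_lag))
  expect_equal(fit$mu, 0)
  expect_error(division_rate(fit), "censored")
})

test_that("median lag recovery error stays under 15 min at sigma_OD = 0.005", {
  errs <- vapply(1:100, function(r) {
    s <- make_od_series(noise_sd = 0.005, seed = 5000 + r)
    fit <- fit_threshold_linear(s$time, s$od)
    abs(fit$t_lag - 200)
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 15)
})

test_that("OD converts linearly to dry cell weight", {
  expect_equal(od_to_dcw(1, 1), 0.4)
  expect_equal(od_to_dcw(0, 1), 0)
  expect_equal(od_to_dcw(0.5, 0.032), 0.0064)
})

test_that("TI feedrate follows the dispense arithmetic and scalings", {
  sch <- pulse_schedule(period = 4, dose_volume = 22,
                        dose_concentration = 2.5, culture_volume = 32)
  expect_equal(ti_feedrate(sch, 0.5), 0.7155, tolerance = 1e-3)
  expect_equal(ti_feedrate(pulse_schedule(4, dose_volume = 0), 0.5), 0)
  # halving the period doubles f; doubling the dose doubles f; doubling
  # od_i halves f
  expect_equal(ti_feedrate(pulse_schedule(2), 0.5),
               2 * ti_feedrate(pulse_schedule(4), 0.5))
  expect_equal(ti_feedrate(pulse_schedule(4, dose_volume = 44), 0.5),
               2 * ti_feedrate(pulse_schedule(4, dose_volume = 22), 0.5))
  expect_equal(ti_feedrate(sch, 1.0), ti_feedrate(sch, 0.5) / 2)
})

test_that("division rate normalizes the post-lag slope to initial amount", {
  s <- make_od_series(od_i = 0.25, t_lag = 100, mu = 5e-4)
  fit <- fit_threshold_linear(s$time, s$od)
  expect_equal(division_rate(fit), 0.12, tolerance = 1e-4)
  s2 <- make_od_series(od_i = 0.50, t_lag = 100, mu = 5e-4)
  fit2 <- fit_threshold_linear(s2$time, s2$od)
  expect_equal(division_rate(fit2), division_rate(fit) / 2,
               tolerance = 1e-4)
})

test_that("lag decay curve is recovered exactly from noise-free points", {
  f <- c(0.2, seq(0.25, 0.6, by = 0.05))
  lag <- c(NA, 380 * exp(-4 * (f[-1] - 0.2)))   # f = 0.2 censored
  fit <- fit_lag_vs_feedrate(f, lag)
  expect_equal(unname(coef(fit)), c(0.2, 380, 4), tolerance = 1e-8)
  expect_true(is.na(predict(fit, 0.1)))         # indeterminate below p0
  expect_equal(predict(fit, 0.3), 380 * exp(-4 * 0.1), tolerance = 1e-6)
  expect_error(fit_lag_vs_feedrate(f[-1], rep(100, 8)), "degenerate")
})

test_that("maintenance decomposition recovers yield and intercept", {
  # exact line: lm warns that the fit is perfect, which is the point here
  fit <- suppressWarnings(
    decompose_maintenance(c(0.01, 0.02, 0.03), c(0.2, 0.4, 0.6)))
  expect_equal(fit$yield_xs, 0.05, tolerance = 1e-10)
  expect_equal(fit$m_s, 0, tolerance = 1e-10)

  set.seed(42)
  psi <- seq(0.005, 0.05, length.out = 20)
  fr <- 20 * psi + 0.05 + rnorm(20, 0, 0.01)
  nf <- decompose_maintenance(psi, fr)
  expect_lt(abs(nf$m_s - 0.05), 2 * nf$m_s_se)
  expect_error(decompose_maintenance(rep(0.01, 3), c(0.2, 0.3, 0.4)),
               "degenerate")
})
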