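test_that("synthesis rate combines basal and feed-coupled terms", {
  p <- ref_params()
  expect_equal(synthesis_rate(p, 0), 5)
  expect_equal(synthesis_rate(p, 0.6), 65)
  p0 <- update_params_test(p, alpha0 = 0, alpha1 = 0)
  expect_equal(synthesis_rate(p0, c(0, 0.3, 7)), c(0, 0, 0))
})

test_that("steady state matches the numeric fixed point and saturates", {
  p <- ref_params()
  expect_equal(steady_state(p, 0.2), 1000)
  # oracle: root of a - vmax z/(km + z)
  a <- synthesis_rate(p, 0.2)
  root <- uniroot(function(z) a - p$vmax * z / (p$km + z),
                  c(0, 1e7), tol = 1e-12)$root
  expect_equal(steady_state(p, 0.2), root, tolerance = 1e-8)
  expect_identical(steady_state(p, 0.5), Inf)    # a = 55 >= vmax
  pz <- update_params_test(p, alpha0 = 0)
  expect_equal(steady_state(pz, 0), 0)
})

test_that("critical feedrate is where the steady state meets the threshold", {
  p <- ref_params()
  fc <- critical_feedrate(p)
  expect_equal(fc, (50 * 2000 / 3000 - 5) / 100, tolerance = 1e-12)
  # oracle: bisection on finiteness of the lag
  lo <- 0; hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (is.finite(lag_time_analytic(p, mid))) hi <- mid else lo <- mid
  }
  expect_equal(fc, (lo + hi) / 2, tolerance = 1e-9)
  # basal synthesis already above degradation at threshold
  p_hi <- update_params_test(p, alpha0 = 40)
  expect_equal(critical_feedrate(p_hi), 0)
  expect_error(critical_feedrate(update_params_test(p, alpha1 = 0)),
               "alpha1")
})

test_that("analytic lag reproduces frozen values and sentinels", {
  p <- ref_params()
  expect_equal(lag_time_analytic(p, 0.6), 28.47772, tolerance = 1e-6)
  expect_identical(lag_time_analytic(p, 0.2), Inf)
  p_at <- update_params_test(p, z_init = p$z_threshold)
  expect_equal(lag_time_analytic(p_at, 0.6), 0)
  expect_error(lag_time_analytic(update_params_test(p, z_init = 3000), 0.6),
               "z_init")
})

test_that("numeric lag handles trivial and infinite cases", {
  p <- ref_params()
  expect_identical(lag_time_numeric(p, 0), Inf)   # starvation never triggers
  p_at <- update_params_test(p, z_init = p$z_threshold)
  expect_equal(lag_time_numeric(p_at, 0.6), 0)
  # horizon too short but crossing provably eventual -> undetermined
  res <- lag_time_numeric(p, 0.6, t_max = 1)
  expect_true(is.na(res))
  expect_identical(attr(res, "status"), "undetermined")
})

test_that("starvation trajectory depletes toward the f = 0 steady state", {
  p <- update_params_test(ref_params(), z_init = 5000)
  tr <- starvation_trajectory(p, t_max = 300, n_steps = 300)
  # initial slope from the model right-hand side: 5 - 50*5000/6000
  slope0 <- (tr$z[2] - tr$z[1]) / (tr$times[2] - tr$times[1])
  expect_equal(slope0, 5 - 50 * 5000 / 6000, tolerance = 1e-2)
  expect_true(all(diff(tr$z) <= 1e-9))
  expect_gt(tr$z[length(tr$z)], steady_state(p, 0) - 1)

  # degradation knocked out: linear rise, no depletion
  p_ko <- update_params_test(ref_params(), vmax = 0)
  tr_ko <- starvation_trajectory(p_ko, t_max = 100)
  expect_true(all(diff(tr_ko$z) >= 0))
  expect_equal(tr_ko$z[length(tr_ko$z)], p_ko$z_init + p_ko$alpha0 * 100,
               tolerance = 1e-6)

  # started at the fixed point: constant
  zss <- steady_state(ref_params(), 0)
  p_fix <- update_params_test(ref_params(), z_init = zss)
  tr_fix <- starvation_trajectory(p_fix, t_max = 200)
  expect_equal(max(abs(tr_fix$z - zss)), 0, tolerance = 1e-6)
})

test_that("pulse train counts discrete doses and matches the smoothed limit", {
  # pure bookkeeping: no synthesis/degradation between pulses, 100
  # copies per pulse from Z0 = 1000 to threshold 2000 -> 10th pulse, t = 90
  p <- ftsz_params(alpha0 = 0, alpha1 = 100, vmax = 0, km = 1000,
                   z_threshold = 2000, z_init = 1000)
  tr <- simulate_pulse_train(p, period = 10, dose = 100 / (100 * 60),
                             t_max = 200)
  expect_equal(tr$lag_time, 90)

  # dose = 0 reduces to the starvation trajectory
  pr <- ref_params()
  tr0 <- simulate_pulse_train(pr, period = 10, dose = 0, t_max = 300)
  st <- starvation_trajectory(pr, t_max = 300)
  expect_identical(tr0$lag_time, st$lag_time)
  expect_equal(tr0$z[length(tr0$z)], st$z[length(st$z)], tolerance = 1e-6)
  expect_error(simulate_pulse_train(pr, period = 10, dose = -1),
               "dose")
})

test_that("lag is strictly decreasing in feedrate and diverges at the critical rate", {
  p <- ref_params()
  fc <- critical_feedrate(p)
  fs <- fc + c(1e-9, 1e-6, 1e-4, 1e-2, 0.05, seq(0.1, 2, by = 0.1))
  lags <- lag_time_analytic(p, fs)
  expect_true(all(is.finite(lags)))
  expect_true(all(diff(lags) < 0))
  # unbounded (logarithmic) growth approaching the critical rate
  expect_gt(lags[1], 3 * lag_time_analytic(p, fc + 1e-2))
  expect_identical(lag_time_analytic(p, fc * (1 - 1e-9)), Inf)
})

test_that("total glucose to division rises as feedrate falls toward critical", {
  p <- ref_params()
  fc <- critical_feedrate(p)
  fs <- fc + seq(0.02, 1, by = 0.02)
  total <- fs * lag_time_analytic(p, fs)
  # walking f downward toward f_crit increases f * lag(f)
  expect_true(all(diff(total) < 0))
})

test_that("titration scaling moves the lag in the expected directions", {
  p <- ref_params()
  f <- 0.6
  expect_equal(predict_titration(p, 1, 1, f), lag_time_analytic(p, f))
  lag_v <- vapply(c(0.5, 1, 1.5), function(sv)
    predict_titration(p, 1, sv, f), numeric(1))
  expect_true(all(diff(lag_v) > 0))
  lag_a <- vapply(c(0.8, 1, 1.3, 2), function(sa)
    predict_titration(p, sa, 1, f), numeric(1))
  expect_true(all(diff(lag_a) < 0))
  # full protease inhibition: linear rise, Km drops out
  a <- synthesis_rate(p, f)
  expect_equal(predict_titration(p, 1, 0, f),
               (p$z_threshold - p$z_init) / a, tolerance = 1e-12)
  expect_lt(predict_titration(p, 1, 0, f), lag_time_analytic(p, f))
})

test_that("parameter validation rejects malformed sets", {
  expect_error(ftsz_params(-1, 100, 50, 1000, 2000, 1000), "non-negative")
  expect_error(ftsz_params(5, 100, 50, 0, 2000, 1000), "km")
  expect_error(ftsz_params(5, 100, 50, 1000, 0, 1000), "z_threshold")
  expect_error(ftsz_params(5, NA, 50, 1000, 2000, 1000), "finite")
})
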