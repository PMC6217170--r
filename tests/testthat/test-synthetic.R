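test_that("generators are byte-identical under a fixed seed", {
  cfg <- synth_config(seed = 5)
  a <- gen_od_experiment(cfg, 0.6)
  b <- gen_od_experiment(cfg, 0.6)
  expect_identical(a, b)
  expect_identical(gen_lag_dataset(cfg, c(0.3, 0.5)),
                   gen_lag_dataset(cfg, c(0.3, 0.5)))
  expect_identical(gen_cytometry_timecourse(cfg),
                   gen_cytometry_timecourse(cfg))
  expect_identical(gen_ion_traces(cfg, "spike"),
                   gen_ion_traces(cfg, "spike"))
  # different seeds decorrelate
  cfg2 <- synth_config(seed = 6)
  expect_false(identical(gen_od_experiment(cfg2, 0.6)$od, a$od))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(gen_od_experiment(synth_config(seed = 5), 0.6))
  expect_identical(runif(1), before)
})

test_that("noise-free OD generation closes the loop with the changepoint fit", {
  cfg <- synth_config(seed = 8, od_sd = 0)
  e <- gen_od_experiment(cfg, 0.6)
  fit <- fit_threshold_linear(e$time, e$od)
  expect_equal(fit$od_i, e$truth$od_i, tolerance = 1e-8)
  expect_equal(fit$t_lag, e$truth$t_lag, tolerance = 1e-3)
  expect_equal(fit$mu, e$truth$mu, tolerance = 1e-6)
})

test_that("sub-critical feedrates yield flat, censored experiments", {
  cfg <- synth_config(seed = 9)
  fc <- critical_feedrate(cfg$model)
  e <- gen_od_experiment(cfg, fc * 0.5)
  expect_true(e$truth$censored)
  fit <- fit_threshold_linear(e$time, e$od)
  expect_true(fit$censored)

  d <- gen_lag_dataset(cfg, c(fc * 0.3, fc * 0.6))
  expect_true(all(is.na(d$lag_min)))
})

test_that("noise-free lag dataset closes the loop with the gain fit", {
  cfg <- synth_config(seed = 10, lag_sd_log10 = 0)
  d <- gen_lag_dataset(cfg, seq(0.3, 0.9, by = 0.1))
  fit <- fit_alpha1(lag_min ~ feedrate_mmol_g_h, data = d,
                    params = cfg$model)
  expect_lt(abs(fit$alpha1_hat - cfg$model$alpha1) / cfg$model$alpha1,
            1e-3)
  expect_equal(fit$r_squared_log10, 1, tolerance = 1e-8)
})

test_that("cytometry pipeline closes the loop on generated data", {
  cfg <- synth_config(seed = 12)
  tc <- gen_cytometry_timecourse(cfg)
  tt <- sort(unique(tc$samples$time_min))
  e_i <- calibrate_expected_events(
    tc$samples$e_total[tc$samples$time_min %in% tt[1:3]])
  rows <- lapply(tt, function(t0) {
    s <- tc$samples[tc$samples$time_min == t0, ]
    c_s <- mean(absolute_count(s$e_cells, s$e_total, e_i))
    fl <- tc$fl1$fl1[tc$fl1$time_min == t0]
    subpopulation_counts(c_s, fit_dna_mixture(fl))
  })
  n1 <- vapply(rows, `[[`, numeric(1), "n1")
  n2 <- vapply(rows, `[[`, numeric(1), "n2")
  truth <- tc$truth
  expect_lt(max(abs(n1 - truth$n1) / (truth$n1 + truth$n2)), 0.05)
  res <- check_2n_to_1n(tt, n1, n2, tolerance = 0.05)
  expect_true(res$consistent)
})

test_that("unclogged samples return raw event counts", {
  cfg <- synth_config(seed = 13, clog_range = c(1, 1))
  tc <- gen_cytometry_timecourse(cfg)
  e_i <- calibrate_expected_events(tc$samples$e_total[1:3])
  c_s <- absolute_count(tc$samples$e_cells, tc$samples$e_total, e_i)
  expect_equal(c_s, tc$samples$e_cells * e_i / tc$samples$e_total)
  expect_equal(mean(abs(c_s - tc$samples$e_cells) / tc$samples$e_cells), 0,
               tolerance = 0.01)
})

test_that("gen_all writes a complete, reloadable input set", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(seed = 14)
  files <- gen_all(cfg, dir)
  expect_true(all(file.exists(files)))
  lags <- read.csv(file.path(dir, "lags.csv"))
  expect_true(all(c("experiment_id", "feedrate_mmol_g_h", "lag_min")
                  %in% names(lags)))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$model$alpha1, cfg$model$alpha1)
  expect_equal(truth$critical_feedrate, critical_feedrate(cfg$model),
               tolerance = 1e-12)
})
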