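#' Configuration for the synthetic-data generators
#'
#' Bundles the model parameterization and noise levels under which the
#' generators emulate the study's inputs, with a single master seed that
#' fans out deterministically to per-generator child seeds (so streams are
#' independent yet fully reproducible: the same seed gives byte-identical
#' outputs).
#'
#' @param seed integer master seed.
#' @param model an [ftsz_params()] object; defaults to the
#'   study-calibrated set ([ftsz_params_study()]).
#' @param od_sd additive OD noise, OD units. Default 0.005.
#' @param lag_sd_log10 multiplicative lag noise on the `log10` scale.
#'   Default 0.05.
#' @param yield_xs yield, g DCW per mmol substrate, linking feedrate to
#'   division rate. Default 0.05.
#' @param m_s maintenance feedrate, mmol/g/h. Default 0 (empirically
#'   indistinguishable from zero).
#' @param od_i nominal OD at the onset of pulsing. Default 0.25.
#' @param fl1_mu2,fl1_sd 2N fluorescence mean and common component sd
#'   (the 1N mean is half of `fl1_mu2`). Defaults 200 and 15.
#' @param events_nominal expected total events per unclogged injection.
#'   Default 10000.
#' @param clog_range range of the per-sample clogging attenuation factor
#'   for post-calibration samples. Default `c(0.6, 1)`.
#' @param ion_noise_sd additive noise of the Z-scale ion traces.
#'   Default 0.3.
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1L, model = ftsz_params_study(),
                         od_sd = 0.005, lag_sd_log10 = 0.05,
                         yield_xs = 0.05, m_s = 0, od_i = 0.25,
                         fl1_mu2 = 200, fl1_sd = 15,
                         events_nominal = 10000,
                         clog_range = c(0.6, 1), ion_noise_sd = 0.3) {
  stopifnot(inherits(model, "ftsz_params"), od_sd >= 0, lag_sd_log10 >= 0,
            yield_xs > 0, od_i > 0, fl1_mu2 > 0, fl1_sd > 0,
            events_nominal > 0, ion_noise_sd >= 0,
            length(clog_range) == 2L, clog_range[1] > 0,
            clog_range[2] <= 1, clog_range[1] <= clog_range[2])
  structure(list(seed = as.integer(seed), model = model, od_sd = od_sd,
                 lag_sd_log10 = lag_sd_log10, yield_xs = yield_xs,
                 m_s = m_s, od_i = od_i, fl1_mu2 = fl1_mu2,
                 fl1_sd = fl1_sd, events_nominal = events_nominal,
                 clog_range = clog_range, ion_noise_sd = ion_noise_sd),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic-data configuration (seed", x$seed, ")\n")
  cat(sprintf("  od_sd = %g, lag_sd_log10 = %g, yield = %g, m_s = %g\n",
              x$od_sd, x$lag_sd_log10, x$yield_xs, x$m_s))
  cat(sprintf("  FL1: N(%g, %g^2) + N(%g, %g^2); events %g, clog [%g, %g]\n",
              x$fl1_mu2 / 2, x$fl1_sd, x$fl1_mu2, x$fl1_sd,
              x$events_nominal, x$clog_range[1], x$clog_range[2]))
  invisible(x)
}

#' Generate a synthetic OD time course for one pulse-feeding experiment
#'
#' Emulates an OD record: flat at `od_i` until the model-implied lag time,
#' then linear growth with slope `mu = Psi od_i / 60` where the division
#' rate follows the yield decomposition `Psi = Y (f - m_s)`; additive
#' Gaussian measurement noise throughout. Sub-critical feedrates give a
#' flat (censored) trace. The generating truth is returned alongside so
#' recovery can be tested in a closed loop.
#'
#' @param config a [synth_config()].
#' @param f TI feedrate, mmol/g/h.
#' @param duration record length, minutes.
#' @param dt sampling interval, minutes.
#' @param rep_id replicate index, offsets the child seed so replicate
#'   experiments are independent.
#' @return A list with `time`, `od`, and `truth` (list: `od_i`, `t_lag`,
#'   `mu`, `psi`, `censored`).
#' @export
gen_od_experiment <- function(config, f, duration = 500, dt = 5,
                              rep_id = 0L) {
  stopifnot(inherits(config, "synth_config"), dt > 0, duration > dt, f >= 0)
  t_lag <- lag_time_analytic(config$model, f)
  psi <- max(0, config$yield_xs * (f - config$m_s))
  mu <- psi * config$od_i / 60
  tt <- seq(0, duration, by = dt)
  censored <- !is.finite(t_lag) || t_lag > duration
  base <- if (censored) rep(config$od_i, length(tt))
          else config$od_i + mu * pmax(0, tt - t_lag)
  od <- with_seed(child_seed(config$seed, 11L + 97L * rep_id),
                  base + stats::rnorm(length(tt), 0, config$od_sd))
  list(time = tt, od = pmax(od, 0),
       truth = list(od_i = config$od_i,
                    t_lag = if (censored) NA_real_ else t_lag,
                    mu = if (censored) 0 else mu,
                    psi = if (censored) 0 else psi,
                    censored = censored))
}

#' Generate a synthetic lag-versus-feedrate dataset
#'
#' Emulates the pulse-frequency experiment series: each feedrate's lag is
#' the analytic model lag perturbed by multiplicative `log10`-normal
#' noise; feedrates at or below the critical rate are emitted as censored
#' (`NA` lag, non-dividing within the observation window).
#'
#' @param config a [synth_config()].
#' @param feedrates vector of TI feedrates, mmol/g/h.
#' @param rep_id replicate index (seed offset).
#' @return A data frame with columns `experiment_id`,
#'   `feedrate_mmol_g_h`, `lag_min` (`NA` = censored), plus attribute
#'   `"truth"` (the generating `alpha1` and parameter set).
#' @export
gen_lag_dataset <- function(config, feedrates, rep_id = 0L) {
  stopifnot(inherits(config, "synth_config"), all(feedrates >= 0))
  base <- lag_time_analytic(config$model, feedrates)
  noise <- with_seed(child_seed(config$seed, 23L + 97L * rep_id),
                     stats::rnorm(length(feedrates), 0, config$lag_sd_log10))
  lag <- ifelse(is.finite(base), base * 10^noise, NA_real_)
  out <- data.frame(experiment_id = sprintf("synth_%02d", seq_along(feedrates)),
                    feedrate_mmol_g_h = feedrates,
                    lag_min = lag)
  attr(out, "truth") <- list(alpha1 = config$model$alpha1,
                             params = config$model)
  out
}

#' Generate a synthetic flow-cytometry time course
#'
#' Emulates the refeeding time course in which the replicated (2N) pool
#' drains after the lag while each division deposits two 1N daughters:
#' `n2(t)` decays exponentially past the lag and
#' `n1(t) = n1(0) + 2 (n2(0) - n2(t))`. Each time point is measured by
#' `n_replicates` independent injections (the acquisition protocol takes
#' two to three per time point). Per injection, total events are the
#' nominal count attenuated by a clogging factor (1 at the first three,
#' calibration, time points); gated cell events are binomial in the true
#' cell fraction, and per-cell DNA fluorescence is drawn from the
#' two-component mixture with weights `n1 : n2`.
#'
#' @param config a [synth_config()].
#' @param times sampling times, minutes.
#' @param n1_0,n2_0 initial subpopulation counts per injection volume.
#' @param t_lag lag before 2N draining begins, minutes.
#' @param k_drain exponential drain rate of the 2N pool, min^-1.
#' @param n_replicates injections per time point. Default 3.
#' @return A list with `samples` (data frame: `time_min`, `replicate`,
#'   `e_cells`, `e_total`), `fl1` (long data frame: `time_min`,
#'   `replicate`, `fl1`), and `truth` (data frame: `time_min`, `n1`,
#'   `n2`).
#' @export
gen_cytometry_timecourse <- function(config, times = seq(0, 300, by = 30),
                                     n1_0 = 600, n2_0 = 400, t_lag = 60,
                                     k_drain = 0.01, n_replicates = 3L) {
  stopifnot(inherits(config, "synth_config"), length(times) >= 3L,
            n1_0 >= 0, n2_0 >= 0, k_drain >= 0, n_replicates >= 1L)
  n2 <- n2_0 * exp(-k_drain * pmax(0, times - t_lag))
  n1 <- n1_0 + 2 * (n2_0 - n2)
  e_nom <- config$events_nominal
  nt <- length(times); nr <- n_replicates
  idx_t <- rep(seq_len(nt), each = nr)
  with_seed(child_seed(config$seed, 37L), {
    clog <- ifelse(idx_t <= 3L, 1,
                   stats::runif(nt * nr, config$clog_range[1],
                                config$clog_range[2]))
    e_total <- round(e_nom * clog)
    p_cell <- pmin((n1 + n2) / e_nom, 1)[idx_t]
    e_cells <- stats::rbinom(nt * nr, e_total, p_cell)
    fl1 <- lapply(seq_len(nt * nr), function(s) {
      i <- idx_t[s]
      n <- e_cells[s]
      is2n <- stats::runif(n) < n2[i] / (n1[i] + n2[i])
      mu <- ifelse(is2n, config$fl1_mu2, config$fl1_mu2 / 2)
      data.frame(time_min = times[i],
                 replicate = ((s - 1L) %% nr) + 1L,
                 fl1 = stats::rnorm(n, mu, config$fl1_sd))
    })
    list(samples = data.frame(time_min = times[idx_t],
                              replicate = rep(seq_len(nr), nt),
                              e_cells = e_cells, e_total = e_total),
         fl1 = do.call(rbind, fl1),
         truth = data.frame(time_min = times, n1 = n1, n2 = n2))
  })
}

#' Generate synthetic pulse-locked ion traces
#'
#' Emulates the real-time metabolomics morphologies on the Z scale:
#' `spike` traces jump at each pulse and decay exponentially back to
#' baseline; `accumulate-deplete` traces rise linearly between pulses and
#' reset at each pulse; `flat` traces are noise only. All traces carry
#' additive Gaussian noise of sd `ion_noise_sd`.
#'
#' @param config a [synth_config()].
#' @param classes character vector of labels from
#'   `c("spike", "accumulate-deplete", "flat")`, one trace per entry.
#' @param pulse_period pulse period, seconds. Default 400.
#' @param duration trace length, seconds. Default 2000.
#' @param dt sampling interval, seconds. Default 5.
#' @param t_start time of the first pulse, seconds; the interval before
#'   it is a quiet baseline usable as a Z-normalization reference window.
#'   Default 0 (pulsing from the start).
#' @param spike_amplitude peak Z of a noiseless spike. Default 6.
#' @param spike_tau spike decay constant, seconds. Default 60.
#' @param saw_amplitude sawtooth rise per interval, Z units. Default 5.
#' @return A list of traces; each has `time`, `z` (noisy, on the Z
#'   scale), `pulse_times`, and `truth_class`.
#' @export
gen_ion_traces <- function(config, classes, pulse_period = 400,
                           duration = 2000, dt = 5, t_start = 0,
                           spike_amplitude = 6, spike_tau = 60,
                           saw_amplitude = 5) {
  stopifnot(inherits(config, "synth_config"),
            all(classes %in% c("spike", "accumulate-deplete", "flat")),
            pulse_period > 0, dt > 0, t_start >= 0)
  tt <- seq(0, duration, by = dt)
  pulses <- seq(t_start, duration - pulse_period / 2, by = pulse_period)
  since <- function(t) {
    k <- findInterval(t, pulses)
    if (k == 0) NA_real_ else t - pulses[k]
  }
  lapply(seq_along(classes), function(i) {
    cl <- classes[i]
    s <- vapply(tt, since, numeric(1))
    base <- switch(cl,
      "spike" = ifelse(is.na(s), 0, spike_amplitude * exp(-s / spike_tau)),
      "accumulate-deplete" = ifelse(is.na(s), 0,
                                    saw_amplitude * s / pulse_period),
      "flat" = rep(0, length(tt)))
    z <- with_seed(child_seed(config$seed, 53L + 97L * i),
                   base + stats::rnorm(length(tt), 0, config$ion_noise_sd))
    structure(list(time = tt, z = z, pulse_times = pulses,
                   truth_class = cl),
              class = "synthetic_ion_trace")
  })
}

#' Write a complete synthetic input set to disk
#'
#' Materializes every input the pipeline consumes — OD time courses with
#' their pulse schedules, a lag-versus-feedrate table, a cytometry time
#' course, and ion traces — as plain CSV files plus a `truth.json` holding
#' the generating parameters.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if missing).
#' @param feedrates feedrates of the lag/OD experiment series. The
#'   default emulates the experimental design: 18 feedrates spanning 0.1
#'   to 1 mmol/g/h, including one just below the critical rate.
#' @return Invisibly, the list of files written.
#' @export
gen_all <- function(config, dir,
                    feedrates = c(0.1, 0.18, seq(0.25, 1, by = 0.05))) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(x, name) {
    path <- file.path(dir, name)
    utils::write.csv(x, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  lags <- gen_lag_dataset(config, feedrates)
  wr(lags, "lags.csv")

  od_rows <- lapply(seq_along(feedrates), function(i) {
    e <- gen_od_experiment(config, feedrates[i], rep_id = i)
    data.frame(experiment_id = sprintf("synth_%02d", i),
               time_min = e$time, od = e$od)
  })
  wr(do.call(rbind, od_rows), "od.csv")

  cyto <- gen_cytometry_timecourse(config)
  wr(cyto$samples, "cytometry_counts.csv")
  wr(cyto$fl1, "cytometry_fl1.csv")

  # traces are written as raw ion counts (baseline 1000, 100 counts per Z
  # unit) with a quiet 300 s reference window before pulsing starts, so
  # the pipeline exercises the Z-normalization step
  ions <- gen_ion_traces(config, c("spike", "accumulate-deplete", "flat"),
                         t_start = 300, duration = 2300)
  ion_rows <- do.call(rbind, lapply(seq_along(ions), function(i)
    data.frame(ion_id = sprintf("ion_%02d", i), time_s = ions[[i]]$time,
               intensity = pmax(1000 + 100 * ions[[i]]$z, 0))))
  wr(ion_rows, "ion_traces.csv")
  wr(data.frame(time_s = ions[[1]]$pulse_times), "ion_pulses.csv")

  truth <- list(seed = config$seed,
                model = unclass(config$model),
                yield_xs = config$yield_xs, m_s = config$m_s,
                od_i = config$od_i,
                critical_feedrate = critical_feedrate(config$model),
                ion_classes = vapply(ions, `[[`, character(1), "truth_class"),
                cytometry_truth = cyto$truth)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(files, truth_path))
}
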