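#' Run the full pulse-feeding analysis pipeline
#'
#' Chains the empirical and model stages over a directory of input
#' tables (as produced by [gen_all()] or exported from instruments):
#' \enumerate{
#'   \item growth: per-experiment outlier exclusion and flat-then-linear
#'     changepoint fits of the OD records (`od.csv`), division rates;
#'   \item lag curve: threshold exponential-decay fit of lag versus
#'     feedrate (`lags.csv`), censored experiments constraining the
#'     breakpoint;
#'   \item model: single-parameter fit of the feed-coupled synthesis gain
#'     and the implied critical feedrate;
#'   \item maintenance: yield/maintenance decomposition of the feedrate;
#'   \item optionally, cytometry counting + mixture deconvolution +
#'     division bookkeeping (`cytometry_counts.csv`, `cytometry_fl1.csv`)
#'     and ion-trace normalization + classification (`ion_traces.csv`,
#'     `ion_pulses.csv`), when those files are present.
#' }
#' Results are written as CSV/JSON together with a run manifest (input
#' digests, seed, package version) that makes reruns reproducible.
#'
#' @param input_dir directory holding the input CSV tables. Required:
#'   `lags.csv` (`experiment_id`, `feedrate_mmol_g_h`, `lag_min`).
#'   Optional: `od.csv` (`experiment_id`, `time_min`, `od`), cytometry
#'   and ion tables.
#' @param output_dir directory for results (created if needed).
#' @param params an [ftsz_params()] object fixing all model constants
#'   except the fitted gain, or the result of [read_pulselag_config()].
#' @param seed integer seed recorded in the manifest and used for any
#'   stochastic stage.
#' @return Invisibly, a list with the fitted objects and result paths.
#' @export
run_pipeline <- function(input_dir, output_dir, params, seed = 1L) {
  if (inherits(params, "ftsz_params")) {
    cfg <- list(model = params, fit = list(t_max_fit = 1e4,
                                           exclude_zero_lag = TRUE))
  } else if (is.list(params) && inherits(params$model, "ftsz_params")) {
    cfg <- params
  } else stop("'params' must be an ftsz_params object or a config list")
  if (!dir.exists(input_dir)) stop("input directory not found: ", input_dir)
  lag_path <- file.path(input_dir, "lags.csv")
  if (!file.exists(lag_path))
    stop("validation error: required input 'lags.csv' is missing from ",
         input_dir)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  msg <- function(...) message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "), ...)

  lags <- utils::read.csv(lag_path)
  need <- c("experiment_id", "feedrate_mmol_g_h", "lag_min")
  miss <- setdiff(need, names(lags))
  if (length(miss))
    stop("validation error in lags.csv: missing columns ",
         paste(miss, collapse = ", "))
  bad <- !is.finite(lags$feedrate_mmol_g_h) | lags$feedrate_mmol_g_h < 0
  if (any(bad))
    stop("validation error in lags.csv: invalid feedrate in rows ",
         paste(which(bad), collapse = ", "))
  results <- list()

  # --- growth stage -------------------------------------------------
  od_path <- file.path(input_dir, "od.csv")
  growth_tab <- NULL
  if (file.exists(od_path)) {
    msg("growth: fitting OD records")
    od <- utils::read.csv(od_path)
    growth_tab <- do.call(rbind, lapply(split(od, od$experiment_id),
                                        function(d) {
      d <- d[order(d$time_min), ]
      cl <- exclude_outliers(d$time_min, d$od)
      fit <- fit_threshold_linear(cl$time, cl$od,
                                  n_excluded = cl$n_excluded)
      data.frame(experiment_id = d$experiment_id[1],
                 od_i = fit$od_i, t_lag = fit$t_lag, mu = fit$mu,
                 censored = fit$censored,
                 psi_per_h = if (fit$censored) NA_real_
                             else division_rate(fit),
                 rss = fit$rss, n_excluded = fit$n_excluded)
    }))
    rownames(growth_tab) <- NULL
    utils::write.csv(growth_tab, file.path(output_dir, "growth_fits.csv"),
                     row.names = FALSE)
    results$growth <- growth_tab
  }

  # --- empirical lag curve ------------------------------------------
  msg("lag curve: threshold exponential decay fit")
  p0 <- if (!any(!is.finite(lags$lag_min)))
    critical_feedrate(cfg$model) else NULL
  decay <- fit_lag_vs_feedrate(lags$feedrate_mmol_g_h, lags$lag_min,
                               p0 = p0)
  results$lag_curve <- decay

  # --- model fit ----------------------------------------------------
  msg("model: fitting feed-coupled synthesis gain")
  fit <- fit_alpha1(lag_min ~ feedrate_mmol_g_h, data = lags,
                    params = cfg$model, t_max_fit = cfg$fit$t_max_fit)
  results$model_fit <- fit
  pred <- data.frame(experiment_id = lags$experiment_id,
                     feedrate_mmol_g_h = lags$feedrate_mmol_g_h,
                     lag_min = lags$lag_min,
                     lag_pred_min = predict(fit, lags$feedrate_mmol_g_h))
  utils::write.csv(pred, file.path(output_dir, "model_predictions.csv"),
                   row.names = FALSE)

  # --- maintenance decomposition ------------------------------------
  maint <- NULL
  if (!is.null(growth_tab)) {
    f_by_id <- lags$feedrate_mmol_g_h[match(growth_tab$experiment_id,
                                            lags$experiment_id)]
    ok <- !growth_tab$censored & is.finite(f_by_id) &
      is.finite(growth_tab$psi_per_h)
    if (sum(ok) >= 3 && stats::sd(growth_tab$psi_per_h[ok]) > 0) {
      msg("maintenance: yield decomposition")
      maint <- decompose_maintenance(growth_tab$psi_per_h[ok],
                                     f_by_id[ok])
      results$maintenance <- maint
    }
  }

  # --- optional cytometry stage -------------------------------------
  cyto_counts <- file.path(input_dir, "cytometry_counts.csv")
  cyto_fl1 <- file.path(input_dir, "cytometry_fl1.csv")
  if (file.exists(cyto_counts) && file.exists(cyto_fl1)) {
    msg("cytometry: counting and mixture deconvolution")
    sm <- utils::read.csv(cyto_counts)
    fl <- utils::read.csv(cyto_fl1)
    tt <- sort(unique(sm$time_min))
    e_i <- calibrate_expected_events(sm$e_total[sm$time_min %in% tt[1:3]])
    # replicate injections per time point: average the corrected counts,
    # pool the fluorescence events for the mixture fit
    rows <- lapply(tt, function(t0) {
      s <- sm[sm$time_min == t0, ]
      c_s <- mean(absolute_count(s$e_cells, s$e_total, e_i))
      mix <- fit_dna_mixture(fl$fl1[fl$time_min == t0])
      n <- subpopulation_counts(c_s, mix)
      data.frame(time_min = t0, c_s = c_s,
                 n1 = n[["n1"]], n2 = n[["n2"]],
                 w2 = mix$w2, mu_ratio = mix$mu2 / mix$mu1)
    })
    cyto_tab <- do.call(rbind, rows)
    division <- check_2n_to_1n(cyto_tab$time_min, cyto_tab$n1, cyto_tab$n2)
    utils::write.csv(cyto_tab, file.path(output_dir, "cytometry_counts_fit.csv"),
                     row.names = FALSE)
    results$cytometry <- list(table = cyto_tab, division = division)
  }

  # --- optional ion-trace stage -------------------------------------
  ion_path <- file.path(input_dir, "ion_traces.csv")
  pulse_path <- file.path(input_dir, "ion_pulses.csv")
  if (file.exists(ion_path) && file.exists(pulse_path)) {
    msg("ions: Z-normalization and pulse-response classification")
    ions <- utils::read.csv(ion_path)
    pulses <- utils::read.csv(pulse_path)$time_s
    ref_end <- min(pulses)
    ion_tab <- do.call(rbind, lapply(split(ions, ions$ion_id), function(d) {
      zt <- z_normalize(d$time_s, d$intensity, c(min(d$time_s), ref_end))
      zt$z <- moving_average(zt$z, 3L)   # suppress acquisition noise
      pr <- pulse_response_features(zt, pulses)
      data.frame(ion_id = d$ion_id[1], class = pr$class,
                 mean_peak_z = mean(pr$features$peak_z))
    }))
    rownames(ion_tab) <- NULL
    utils::write.csv(ion_tab, file.path(output_dir, "ion_classes.csv"),
                     row.names = FALSE)
    results$ions <- ion_tab
  }

  # --- summary + manifest -------------------------------------------
  summary <- list(
    alpha1_hat = fit$alpha1_hat,
    r_squared_log10 = fit$r_squared_log10,
    n_used = fit$n_used,
    critical_feedrate = critical_feedrate(fit$params),
    lag_curve = as.list(coef(decay)),
    maintenance = if (!is.null(maint)) list(yield_xs = maint$yield_xs,
                                            m_s = maint$m_s,
                                            m_s_se = maint$m_s_se))
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  inputs <- list.files(input_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    seed = as.integer(seed),
    package_version = as.character(utils::packageVersion("pulselag")),
    model = unclass(cfg$model),
    fit_settings = cfg$fit,
    input_digests = as.list(tools::md5sum(sort(inputs))))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  msg("done: results in ", output_dir)
  invisible(results)
}
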