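#' Exclude high outliers from an OD series
#'
#' Single-pass, one-sided rule: observations more than three sample
#' standard deviations above the mean of the whole series are dropped.
#' A constant series (zero standard deviation) is left untouched.
#'
#' @param time time points, minutes.
#' @param od optical density values (same length).
#' @return A list with `time`, `od` (retained points) and `n_excluded`.
#' @export
#' @examples
#' out <- exclude_outliers(1:11, c(rep(0.3, 10), 1.0))
#' out$n_excluded  # 1
exclude_outliers <- function(time, od) {
  stopifnot(length(time) == length(od), length(od) >= 4L,
            all(is.finite(time)), all(is.finite(od)), all(od >= 0))
  s <- stats::sd(od)
  keep <- if (s == 0) rep(TRUE, length(od)) else od <= mean(od) + 3 * s
  list(time = time[keep], od = od[keep], n_excluded = sum(!keep))
}

# For a fixed changepoint, the flat-then-linear model
#   OD(t) = od_i + mu * max(0, t - t_lag)
# is linear in (od_i, mu); solve it in closed form with mu constrained >= 0.
od_lag_rss <- function(time, od, t_lag) {
  x <- pmax(0, time - t_lag)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) {
    od_i <- mean(od); mu <- 0
  } else {
    mu <- sum((x - mean(x)) * (od - mean(od))) / sxx
    if (mu < 0) mu <- 0
    od_i <- mean(od) - mu * mean(x)
  }
  res <- od - (od_i + mu * x)
  list(rss = sum(res^2), od_i = od_i, mu = mu, residuals = res)
}

#' Flat-then-linear changepoint fit of an OD growth curve
#'
#' Least-squares fit of the piecewise model
#' \deqn{OD(t) = OD_i \;(t < t_{lag}); \quad OD_i + \mu (t - t_{lag}) \;(t \ge t_{lag})}
#' extracting the pre-division plateau `od_i`, the post-lag slope `mu`
#' (constrained non-negative) and the lag time `t_lag`. For any fixed
#' `t_lag` the remaining parameters are solved linear-algebraically;
#' `t_lag` is profiled over the observed time points and then refined by
#' golden-section search between the bracketing neighbours (ties broken
#' toward the earliest changepoint). When no growth is detectable — the
#' best slope is numerically zero, or the total fitted rise
#' `mu (t_end - t_lag)` does not clear the residual noise floor — the
#' experiment is flagged censored (no division observed within the
#' record) instead of reporting a lag.
#'
#' Outliers should be removed first with [exclude_outliers()].
#'
#' @param time time points, minutes (strictly increasing, >= 6 points).
#' @param od optical density values.
#' @param min_signal minimum total fitted OD rise, in units of the
#'   residual standard deviation, required to call a division event.
#'   Default 5.
#' @param n_excluded number of points removed upstream, carried through
#'   for bookkeeping.
#' @return An object of class `"od_lagfit"`: list with `od_i`, `mu`
#'   (OD/min), `t_lag` (min, `NA` when censored), `censored`, `rss`,
#'   `n_excluded`, and the data.
#' @export
#' @examples
#' tt <- seq(0, 500, by = 5)
#' od <- 0.30 + 5e-4 * pmax(0, tt - 200)
#' fit_threshold_linear(tt, od)
fit_threshold_linear <- function(time, od, min_signal = 5,
                                 n_excluded = 0L) {
  stopifnot(length(time) == length(od), length(od) >= 6L,
            all(diff(time) > 0), all(is.finite(od)))
  flat_rss <- sum((od - mean(od))^2)

  # profile over interior observation times
  grid <- time[time > time[1] & time < time[length(time)]]
  prof <- vapply(grid, function(tl) od_lag_rss(time, od, tl)$rss, numeric(1))
  i_best <- which(prof <= min(prof) + 1e-15 * max(prof, 1))[1]  # earliest tie
  # golden-section refinement between bracketing neighbours
  lo <- if (i_best > 1) grid[i_best - 1] else time[1]
  hi <- if (i_best < length(grid)) grid[i_best + 1] else time[length(time)]
  opt <- stats::optimize(function(tl) od_lag_rss(time, od, tl)$rss,
                         lower = lo, upper = hi, tol = 1e-10)
  cand <- c(opt$minimum, grid[i_best])
  rssv <- c(opt$objective, prof[i_best])
  pick <- which(rssv <= min(rssv) + 1e-15 * max(rssv, 1))
  t_lag <- min(cand[pick])
  best <- od_lag_rss(time, od, t_lag)

  sigma_hat <- sqrt(best$rss / max(length(od) - 3L, 1L))
  rise <- best$mu * (time[length(time)] - t_lag)
  censored <- best$mu <= 1e-10 ||
    (sigma_hat > 0 && rise < min_signal * sigma_hat)
  out <- list(od_i = if (censored) mean(od) else best$od_i,
              mu = if (censored) 0 else best$mu,
              t_lag = if (censored) NA_real_ else t_lag,
              censored = censored,
              rss = if (censored) flat_rss else best$rss,
              n_excluded = as.integer(n_excluded),
              time = time, od = od,
              call = match.call())
  class(out) <- "od_lagfit"
  out
}

#' @export
print.od_lagfit <- function(x, ...) {
  cat("Flat-then-linear OD fit\n")
  if (x$censored) {
    cat(sprintf("  censored: no division detected (OD_i = %.4g)\n", x$od_i))
  } else {
    cat(sprintf("  OD_i = %.4g, t_lag = %.4g min, mu = %.4g OD/min\n",
                x$od_i, x$t_lag, x$mu))
  }
  cat(sprintf("  RSS = %.4g over %d points (%d outliers excluded)\n",
              x$rss, length(x$od), x$n_excluded))
  invisible(x)
}

#' @export
coef.od_lagfit <- function(object, ...)
  c(od_i = object$od_i, mu = object$mu, t_lag = object$t_lag)

#' @export
predict.od_lagfit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$time
       else if (is.data.frame(newdata)) newdata$time else as.numeric(newdata)
  if (object$censored) return(rep(object$od_i, length(t)))
  object$od_i + object$mu * pmax(0, t - object$t_lag)
}

#' @export
residuals.od_lagfit <- function(object, ...)
  object$od - predict(object)

#' @export
plot.od_lagfit <- function(x, ...) {
  graphics::plot(x$time, x$od, xlab = "time (min)", ylab = "OD",
                 col = "grey40", ...)
  graphics::lines(x$time, predict(x), col = "red3", lwd = 2)
  if (!x$censored) graphics::abline(v = x$t_lag, lty = 3)
  invisible(x)
}

#' Convert optical density to dry cell weight
#'
#' Uses the strain/spectrophotometer calibration 1 OD = 0.4 g DCW per
#' litre.
#'
#' @param od optical density (>= 0).
#' @param volume culture volume, litres.
#' @param g_per_od_l calibration constant, g DCW per litre per OD unit.
#' @return Dry cell weight, grams.
#' @export
od_to_dcw <- function(od, volume, g_per_od_l = 0.4) {
  stopifnot(all(od >= 0), all(volume >= 0))
  od * g_per_od_l * volume
}

#' Pulse-feeding schedule
#'
#' Describes a periodic glucose dispense regime: every `period` minutes,
#' `dose_volume` microlitres of a `dose_concentration` g/l glucose
#' solution are added to a `culture_volume` ml culture.
#'
#' @param period minutes between pulse starts (> 0).
#' @param dose_volume microlitres dispensed per pulse.
#' @param dose_concentration glucose concentration of the dispensed
#'   solution, g/l.
#' @param culture_volume culture volume, ml.
#' @param substrate_molar_mass g/mol; default 180.16 (glucose).
#' @return An object of class `"pulse_schedule"`.
#' @export
pulse_schedule <- function(period, dose_volume = 22,
                           dose_concentration = 2.5, culture_volume = 32,
                           substrate_molar_mass = 180.16) {
  vals <- c(period, dose_volume, dose_concentration, culture_volume,
            substrate_molar_mass)
  if (!all(is.finite(vals)) || any(vals <= 0 & c(TRUE, FALSE, TRUE, TRUE, TRUE)))
    stop("schedule fields must be positive (dose_volume may be zero)")
  if (dose_volume < 0) stop("'dose_volume' must be >= 0")
  structure(list(period = period, dose_volume = dose_volume,
                 dose_concentration = dose_concentration,
                 culture_volume = culture_volume,
                 substrate_molar_mass = substrate_molar_mass),
            class = "pulse_schedule")
}

#' @export
print.pulse_schedule <- function(x, ...) {
  cat(sprintf(
    "Pulse schedule: %g ul of %g g/l substrate every %g min into %g ml\n",
    x$dose_volume, x$dose_concentration, x$period, x$culture_volume))
  invisible(x)
}

#' Time-integrated feedrate of a pulse schedule
#'
#' Average substrate supply normalized to the initial dry cell mass:
#' mmol substrate per gram DCW per hour. Each pulse delivers
#' `dose_volume * dose_concentration / substrate_molar_mass` mmol, the
#' culture holds `od_to_dcw(od_i, culture_volume)` grams of cells, and
#' pulses arrive `60/period` times per hour.
#'
#' @param schedule a [pulse_schedule()] object.
#' @param od_i optical density at the onset of pulsing (> 0).
#' @param g_per_od_l OD-to-DCW calibration, g/l per OD.
#' @return Feedrate, mmol g^-1 h^-1.
#' @export
#' @examples
#' ti_feedrate(pulse_schedule(period = 4), od_i = 0.5)  # about 0.72
ti_feedrate <- function(schedule, od_i, g_per_od_l = 0.4) {
  stopifnot(inherits(schedule, "pulse_schedule"), od_i > 0)
  mmol_per_pulse <- schedule$dose_volume * 1e-6 *
    schedule$dose_concentration / schedule$substrate_molar_mass * 1000
  dcw <- od_to_dcw(od_i, schedule$culture_volume / 1000, g_per_od_l)
  mmol_per_pulse / dcw * (60 / schedule$period)
}

#' Division rate from a fitted OD curve
#'
#' The post-lag slope normalized to the initial amount of cells,
#' `Psi = (mu / od_i) * 60`, in units of (new and existing cells per
#' existing cell) per hour.
#'
#' @param fit an [fit_threshold_linear()] result with a finite lag.
#' @return Division rate, h^-1.
#' @export
division_rate <- function(fit) {
  stopifnot(inherits(fit, "od_lagfit"))
  if (fit$censored) stop("censored fit: no division observed, rate undefined")
  (fit$mu / fit$od_i) * 60
}
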