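#' Fit the feedrate-coupled synthesis gain to lag-time data
#'
#' Fits the single free parameter `alpha1` of the FtsZ threshold model by
#' least squares on `log10` lag time: observed lag-versus-feedrate points
#' are compared with [lag_time_analytic()] at trial `alpha1` values, and
#' the squared error of the `log10`-transformed lags is minimized. Points
#' with zero lag are excluded (they carry no information on the
#' accumulation time, only that the threshold was already met); points
#' predicted infinite at a trial `alpha1` enter with `log10(t_max_fit)`,
#' a large finite penalty that keeps the objective smooth and pushes the
#' gain upward. Goodness of fit is the coefficient of determination on the
#' `log10` scale over the points used.
#'
#' The objective is one-dimensional in `log(alpha1)`; it is minimized with
#' `stats::optimize()` over three abutting brackets (a cheap multistart
#' guarding against flat penalty plateaus), ties broken toward the lowest
#' `alpha1`.
#'
#' @param formula a formula `lag ~ feedrate` naming columns of `data`
#'   (lag in minutes, feedrate in mmol/g/h). Alternatively pass numeric
#'   vectors via `lag` and `f`.
#' @param data a data frame holding the variables of `formula`.
#' @param params an [ftsz_params()] object; every field except `alpha1`
#'   is held fixed (its `alpha1` is ignored).
#' @param lag,f numeric vectors, used when `formula` is missing.
#' @param t_max_fit finite stand-in lag (minutes) for points predicted
#'   non-dividing at a trial `alpha1`. Default `1e4`.
#' @param interval search interval for `alpha1`.
#' @return An object of class `"ftsz_fit"` with components `alpha1_hat`,
#'   `r_squared_log10`, `n_used`, `params` (with the fitted `alpha1`),
#'   `data` (points used, with fitted values), `excluded` (zero-lag and
#'   non-finite points), `objective` (residual sum of squares, log10 scale).
#' @seealso [lag_time_analytic()], [critical_feedrate()]
#' @export
#' @examples
#' p <- ftsz_params_ref()
#' d <- data.frame(feedrate = seq(0.35, 0.95, by = 0.1))
#' d$lag <- lag_time_analytic(p, d$feedrate)
#' fit <- fit_alpha1(lag ~ feedrate, data = d, params = p)
#' coef(fit)
fit_alpha1 <- function(formula, data, params, lag = NULL, f = NULL,
                       t_max_fit = 1e4, interval = c(1e-6, 1e8)) {
  stopifnot(inherits(params, "ftsz_params"), t_max_fit > 0)
  if (!missing(formula)) {
    mf <- stats::model.frame(formula, data)
    lag <- mf[[1L]]
    f <- mf[[2L]]
  }
  stopifnot(is.numeric(lag), is.numeric(f), length(lag) == length(f))

  keep <- is.finite(lag) & lag > 0 & is.finite(f) & f >= 0
  excluded <- data.frame(feedrate = f[!keep], lag = lag[!keep])
  f_use <- f[keep]; lag_use <- lag[keep]
  if (length(lag_use) < 1L)
    stop("no usable points: all lags are zero, censored, or non-finite")

  obs_log <- log10(lag_use)
  pred_log <- function(a1) {
    p <- update_params(params, alpha1 = a1)
    pl <- lag_time_analytic(p, f_use)
    pl[!is.finite(pl)] <- t_max_fit
    log10(pmax(pl, .Machine$double.xmin))
  }
  sse <- function(la1) sum((obs_log - pred_log(exp(la1)))^2)

  lo <- log(interval[1]); hi <- log(interval[2])
  cuts <- seq(lo, hi, length.out = 4L)
  cands <- lapply(1:3, function(i)
    stats::optimize(sse, lower = cuts[i], upper = cuts[i + 1L], tol = 1e-12))
  objs <- vapply(cands, `[[`, numeric(1), "objective")
  mins <- vapply(cands, `[[`, numeric(1), "minimum")
  best <- which(objs <= min(objs) + 1e-12)
  la1 <- min(mins[best])                      # tie-break: lowest alpha1
  # polish: optimize() brackets can stop short on a plateau edge
  pol <- stats::optimize(sse, lower = la1 - 2, upper = la1 + 2, tol = 1e-12)
  if (pol$objective < sse(la1)) la1 <- pol$minimum
  a1_hat <- exp(la1)

  fitted_log <- pred_log(a1_hat)
  rss <- sum((obs_log - fitted_log)^2)
  sst <- sum((obs_log - mean(obs_log))^2)
  r2 <- if (length(obs_log) == 1L || sst == 0) {
    if (rss < 1e-12) 1 else -Inf
  } else 1 - rss / sst

  out <- list(alpha1_hat = a1_hat,
              r_squared_log10 = r2,
              n_used = length(lag_use),
              params = update_params(params, alpha1 = a1_hat),
              data = data.frame(feedrate = f_use, lag = lag_use,
                                log10_lag = obs_log,
                                fitted_log10_lag = fitted_log),
              excluded = excluded,
              objective = rss,
              t_max_fit = t_max_fit,
              call = match.call())
  class(out) <- "ftsz_fit"
  out
}

#' @export
print.ftsz_fit <- function(x, ...) {
  cat("FtsZ threshold model: single-parameter fit\n")
  cat(sprintf("  alpha1 = %.6g copies/cell/min per (mmol/g/h)\n", x$alpha1_hat))
  cat(sprintf("  R^2 (log10 lag) = %.4f on %d points (%d excluded)\n",
              x$r_squared_log10, x$n_used, nrow(x$excluded)))
  cat(sprintf("  implied critical feedrate = %.4g mmol/g/h\n",
              critical_feedrate(x$params)))
  invisible(x)
}

#' @export
coef.ftsz_fit <- function(object, ...) c(alpha1 = object$alpha1_hat)

#' @export
summary.ftsz_fit <- function(object, ...) {
  res <- object$data$log10_lag - object$data$fitted_log10_lag
  structure(list(fit = object,
                 residual_summary = summary(res),
                 rms_log10 = sqrt(mean(res^2))),
            class = "summary.ftsz_fit")
}

#' @export
print.summary.ftsz_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  RMS log10 residual = %.4g\n", x$rms_log10))
  cat("  residuals (log10 lag):\n")
  print(x$residual_summary)
  invisible(x)
}

#' Predict lag times from a fitted threshold model
#'
#' @param object an `"ftsz_fit"` object.
#' @param newdata data frame with a `feedrate` column, or a numeric vector
#'   of feedrates. Defaults to the feedrates used in the fit.
#' @param ... unused.
#' @return Predicted lag times in minutes (`Inf` below the critical
#'   feedrate).
#' @export
predict.ftsz_fit <- function(object, newdata = NULL, ...) {
  f <- if (is.null(newdata)) object$data$feedrate
       else if (is.data.frame(newdata)) newdata$feedrate
       else as.numeric(newdata)
  lag_time_analytic(object$params, f)
}

#' @export
fitted.ftsz_fit <- function(object, ...) 10^object$data$fitted_log10_lag

#' @export
residuals.ftsz_fit <- function(object, ...)
  object$data$log10_lag - object$data$fitted_log10_lag

#' @export
plot.ftsz_fit <- function(x, ...) {
  d <- x$data
  fgrid <- seq(max(min(d$feedrate) * 0.8, critical_feedrate(x$params) * 1.001),
               max(d$feedrate) * 1.1, length.out = 200)
  pred <- lag_time_analytic(x$params, fgrid)
  graphics::plot(d$feedrate, d$lag, log = "y",
                 xlab = "TI feedrate (mmol/g/h)", ylab = "lag time (min)",
                 pch = 19, ...)
  graphics::lines(fgrid, pred, col = "red3")
  graphics::abline(v = critical_feedrate(x$params), lty = 3, col = "grey40")
  invisible(x)
}

#' Simulate lag datasets from a fitted threshold model
#'
#' Draws replicate lag-versus-feedrate datasets at the fitted parameters:
#' each observed feedrate's analytic lag is perturbed by multiplicative
#' `log10`-normal noise.
#'
#' @param object an `"ftsz_fit"` object.
#' @param nsim number of replicate datasets.
#' @param seed integer seed (RNG state is restored on exit).
#' @param sd_log10 noise standard deviation on the `log10` scale; defaults
#'   to the fit's RMS residual.
#' @param ... unused.
#' @return A list of `nsim` data frames with columns `feedrate`, `lag`.
#' @export
simulate.ftsz_fit <- function(object, nsim = 1, seed = NULL,
                              sd_log10 = NULL, ...) {
  if (is.null(sd_log10))
    sd_log10 <- sqrt(mean(residuals(object)^2))
  f <- object$data$feedrate
  base <- lag_time_analytic(object$params, f)
  with_seed(seed, {
    lapply(seq_len(nsim), function(i)
      data.frame(feedrate = f,
                 lag = base * 10^stats::rnorm(length(f), 0, sd_log10)))
  })
}
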