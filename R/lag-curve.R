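#' Threshold exponential-decay fit of lag time versus feedrate
#'
#' Empirical separation of the non-dividing and dividing regimes:
#' \deqn{t_{lag}(f) = p_1 e^{-p_2 (f - p_0)} \; (f \ge p_0); \quad
#'       \mathrm{indeterminate} \; (f < p_0)}
#' Above the breakpoint `p0` the lag decays exponentially with feedrate;
#' below it division does not occur and the lag is indeterminate.
#'
#' The pair `(p0, p1)` is not jointly identifiable from dividing points
#' alone (`p1` and `p0` trade off through `p1 e^{p_2 p_0}`), so the fit is
#' conditional on a breakpoint: censored (non-dividing) experiments bound
#' `p0` from below and the largest censored feedrate is taken as the
#' breakpoint estimate; without censored points `p0` must be supplied
#' (e.g. from [critical_feedrate()]), defaulting to 0 with a warning.
#' Given `p0`, `log(p1)` and `p2` are estimated by ordinary least squares
#' of `log` lag on feedrate over the dividing points with `f >= p0`.
#'
#' @param feedrate feedrates, mmol/g/h.
#' @param lag lag times, minutes; `NA` or `Inf` marks a censored
#'   (non-dividing) experiment.
#' @param p0 optional breakpoint when no censored points are present.
#' @return An object of class `"lag_decay_fit"`: list with `p0`, `p1`
#'   (min), `p2` ((mmol/g/h)^-1), per-point `residuals` (log scale),
#'   `n_censored`, and the data used.
#' @export
#' @examples
#' f <- c(0.2, seq(0.25, 0.6, by = 0.05))
#' lag <- c(NA, 380 * exp(-4 * (f[-1] - 0.2)))
#' fit_lag_vs_feedrate(f, lag)
fit_lag_vs_feedrate <- function(feedrate, lag, p0 = NULL) {
  stopifnot(length(feedrate) == length(lag), all(is.finite(feedrate)),
            all(feedrate >= 0))
  cens <- !is.finite(lag)
  f_fin <- feedrate[!cens]; lag_fin <- lag[!cens]
  if (length(f_fin) < 3L) stop("need >= 3 finite-lag points")
  if (any(lag_fin <= 0)) stop("finite lags must be positive")
  if (stats::sd(lag_fin) == 0)
    stop("degenerate input: all finite lags equal, decay rate unidentifiable")

  if (any(cens)) {
    p0_hat <- max(feedrate[cens])
    if (!is.null(p0) && p0 < p0_hat)
      stop("supplied 'p0' is below a censored (non-dividing) feedrate")
    if (!is.null(p0)) p0_hat <- p0
  } else if (!is.null(p0)) {
    p0_hat <- p0
  } else {
    warning("no censored points and no 'p0' supplied; breakpoint set to 0")
    p0_hat <- 0
  }
  if (p0_hat > min(f_fin))
    stop("breakpoint exceeds a dividing feedrate: inconsistent censoring")

  use <- f_fin >= p0_hat
  x <- f_fin[use] - p0_hat
  y <- log(lag_fin[use])
  ols <- stats::lm(y ~ x)
  p2 <- -unname(stats::coef(ols)[2])
  p1 <- exp(unname(stats::coef(ols)[1]))
  if (p2 <= 0)
    warning("fitted decay constant is non-positive: lag does not shorten with feedrate")

  out <- list(p0 = p0_hat, p1 = p1, p2 = p2,
              feedrate = f_fin[use], lag = lag_fin[use],
              residuals = unname(stats::residuals(ols)),
              n_censored = sum(cens),
              call = match.call())
  class(out) <- "lag_decay_fit"
  out
}

#' @export
print.lag_decay_fit <- function(x, ...) {
  cat("Threshold exponential-decay lag curve\n")
  cat(sprintf("  breakpoint p0 = %.4g mmol/g/h (%d censored experiments)\n",
              x$p0, x$n_censored))
  cat(sprintf("  p1 = %.4g min, p2 = %.4g (mmol/g/h)^-1\n", x$p1, x$p2))
  invisible(x)
}

#' @export
coef.lag_decay_fit <- function(object, ...)
  c(p0 = object$p0, p1 = object$p1, p2 = object$p2)

#' Predict lag from the empirical decay curve
#'
#' @param object a `"lag_decay_fit"`.
#' @param newdata feedrates (vector or data frame with column `feedrate`).
#' @param ... unused.
#' @return Lag times, minutes; `NA` (indeterminate) below the breakpoint.
#' @export
predict.lag_decay_fit <- function(object, newdata = NULL, ...) {
  f <- if (is.null(newdata)) object$feedrate
       else if (is.data.frame(newdata)) newdata$feedrate
       else as.numeric(newdata)
  ifelse(f >= object$p0,
         object$p1 * exp(-object$p2 * (f - object$p0)),
         NA_real_)
}

#' @export
residuals.lag_decay_fit <- function(object, ...) object$residuals

#' @export
plot.lag_decay_fit <- function(x, ...) {
  graphics::plot(x$feedrate, x$lag, log = "y",
                 xlab = "TI feedrate (mmol/g/h)", ylab = "lag time (min)",
                 pch = 19, ...)
  fg <- seq(x$p0, max(x$feedrate), length.out = 200)
  graphics::lines(fg, predict(x, fg), col = "red3")
  graphics::abline(v = x$p0, lty = 3, col = "grey40")
  invisible(x)
}

#' Decompose the feedrate into division and maintenance terms
#'
#' Linear decomposition `f = (1/Y_xs) Psi + m_s`: consumed substrate
#' splits into a division-proportional term (reciprocal yield times the
#' division rate) and a maintenance offset. Ordinary least squares of
#' feedrate on division rate; the slope estimates `1/Y_xs` and the
#' intercept `m_s`, with standard errors from the regression.
#'
#' @param psi division rates, h^-1.
#' @param feedrate matching TI feedrates, mmol/g/h.
#' @return An object of class `"maintenance_fit"`: list with `yield_xs`
#'   (g DCW/mmol), `m_s` and `m_s_se` (mmol/g/h), `slope`, `slope_se`,
#'   and the underlying `lm` fit.
#' @export
#' @examples
#' decompose_maintenance(c(0.01, 0.02, 0.03), c(0.2, 0.4, 0.6))
decompose_maintenance <- function(psi, feedrate) {
  stopifnot(length(psi) == length(feedrate), length(psi) >= 3L,
            all(is.finite(psi)), all(is.finite(feedrate)))
  if (stats::sd(psi) == 0)
    stop("degenerate input: division rates all equal, slope unidentifiable")
  fit <- stats::lm(feedrate ~ psi)
  co <- summary(fit)$coefficients
  slope <- co["psi", "Estimate"]
  if (slope <= 0) stop("non-positive slope: yield undefined")
  out <- list(yield_xs = 1 / slope,
              m_s = co["(Intercept)", "Estimate"],
              m_s_se = co["(Intercept)", "Std. Error"],
              slope = slope,
              slope_se = co["psi", "Std. Error"],
              lm = fit,
              call = match.call())
  class(out) <- "maintenance_fit"
  out
}

#' @export
print.maintenance_fit <- function(x, ...) {
  cat("Feedrate decomposition f = (1/Y_xs) Psi + m_s\n")
  cat(sprintf("  yield Y_xs = %.4g g DCW/mmol (slope %.4g +/- %.2g)\n",
              x$yield_xs, x$slope, x$slope_se))
  cat(sprintf("  maintenance m_s = %.4g +/- %.2g mmol/g/h\n",
              x$m_s, x$m_s_se))
  invisible(x)
}

#' @export
coef.maintenance_fit <- function(object, ...)
  c(yield_xs = object$yield_xs, m_s = object$m_s)
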