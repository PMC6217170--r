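#' Calibrate the expected event count of a cytometry time course
#'
#' The injection port clogs progressively over a time course, depressing
#' the number of events recorded per fixed injection volume. The first
#' three time points, taken before appreciable clogging, calibrate the
#' expected total event count `E_i` (their mean), against which later
#' samples are corrected.
#'
#' @param e_total total event counts of the calibration samples (the
#'   first three time points; more may be supplied).
#' @return `E_i`, the expected total events per injection.
#' @export
calibrate_expected_events <- function(e_total) {
  if (length(e_total) < 3L) stop("need >= 3 calibration samples")
  if (!all(is.finite(e_total)) || any(e_total < 0))
    stop("event counts must be finite and non-negative")
  mean(e_total)
}

#' Clog-corrected absolute cell count
#'
#' `C_s = E_cells / E_total * E_i`: the gated-cell fraction of recorded
#' events, rescaled to the calibrated expected event count, cancels the
#' per-sample clogging attenuation (which suppresses cells and debris
#' alike).
#'
#' @param e_cells gated cell events in the sample.
#' @param e_total total events in the sample (> 0).
#' @param e_i calibrated expected events, from
#'   [calibrate_expected_events()].
#' @return Corrected absolute count per injection volume.
#' @export
#' @examples
#' absolute_count(6000, 8000, 10000)  # 7500
absolute_count <- function(e_cells, e_total, e_i) {
  stopifnot(all(is.finite(c(e_cells, e_total, e_i))),
            all(e_cells >= 0), all(e_cells <= e_total), e_i >= 0)
  if (any(e_total == 0)) stop("e_total = 0: sample fully clogged")
  e_cells / e_total * e_i
}

# log-likelihood of a two-component normal mixture
mix_loglik <- function(x, w, mu, sd) {
  sum(log(w[1] * stats::dnorm(x, mu[1], sd[1]) +
          w[2] * stats::dnorm(x, mu[2], sd[2]) + .Machine$double.xmin))
}

# one EM run from a given initialization
em_run <- function(x, mu, sd, w, max_iter, tol, sd_floor) {
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sd[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sd[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    r1 <- 1 - r2
    w <- c(mean(r1), mean(r2))
    if (any(w < 1e-12)) break
    mu <- c(sum(r1 * x) / sum(r1), sum(r2 * x) / sum(r2))
    sd <- sqrt(c(sum(r1 * (x - mu[1])^2) / sum(r1),
                 sum(r2 * (x - mu[2])^2) / sum(r2)))
    sd <- pmax(sd, sd_floor)
    ll <- mix_loglik(x, w, mu, sd)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(w = w, mu = mu, sd = sd, loglik = ll_old, iterations = it)
}

#' Two-component DNA-content mixture deconvolution
#'
#' Separates the single-chromosome (1N) and replicated (2N) subpopulations
#' of a DNA-stain fluorescence distribution by fitting a two-component
#' Gaussian mixture with expectation-maximization. Initialization follows
#' the doubling structure of the data: the 2N mean starts at the highest
#' density mode and the 1N mean at half of it (no 2:1 constraint is
#' imposed during iteration, since stain nonlinearity may break exact
#' doubling). Five deterministic restarts perturb the initial means; the
#' solution with the best likelihood is kept and components are relabeled
#' so the lower mean is 1N.
#'
#' @param fl1 per-event DNA fluorescence values (>= 100 events).
#' @param max_iter maximum EM iterations per restart.
#' @param tol relative log-likelihood convergence tolerance.
#' @return An object of class `"dna_mixture_fit"`: `w1`, `w2` (weights,
#'   summing to 1), `mu1`, `mu2`, `sd1`, `sd2`, `loglik`, and `degenerate`
#'   (`TRUE` when one component collapses: weight under 0.02 or means
#'   closer than half a pooled standard deviation).
#' @export
#' @examples
#' set.seed(1)
#' x <- c(rnorm(600, 100, 15), rnorm(400, 200, 15))
#' fit_dna_mixture(x)
fit_dna_mixture <- function(fl1, max_iter = 500L, tol = 1e-10) {
  stopifnot(is.numeric(fl1), all(is.finite(fl1)))
  if (length(fl1) < 100L) stop("need >= 100 events for a stable mixture fit")
  x <- as.numeric(fl1)
  dens <- stats::density(x)
  mode2 <- dens$x[which.max(dens$y)]
  s0 <- stats::sd(x)
  sd_floor <- max(1e-8 * max(abs(x), 1), 1e-12)
  inits <- list(c(0.5, 1), c(0.45, 1.1), c(0.55, 0.9), c(0.4, 1.2),
                c(0.6, 0.8))
  best <- NULL
  for (ini in inits) {
    mu0 <- c(mode2 * ini[1], mode2 * ini[2])
    run <- em_run(x, mu = mu0, sd = rep(max(s0 / 2, sd_floor), 2),
                  w = c(0.5, 0.5), max_iter = max_iter, tol = tol,
                  sd_floor = sd_floor)
    if (!is.finite(run$loglik)) next
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (is.null(best))
    stop("EM failed to converge from any initialization; ",
         "check the fluorescence values for degeneracy")
  ord <- order(best$mu)
  w <- best$w[ord]; mu <- best$mu[ord]; sd <- best$sd[ord]
  degenerate <- min(w) < 0.02 ||
    (mu[2] - mu[1]) < 0.5 * sqrt(mean(sd^2))
  out <- list(w1 = w[1], w2 = w[2], mu1 = mu[1], mu2 = mu[2],
              sd1 = sd[1], sd2 = sd[2], loglik = best$loglik,
              iterations = best$iterations, degenerate = degenerate,
              n = length(x))
  class(out) <- "dna_mixture_fit"
  out
}

#' @export
print.dna_mixture_fit <- function(x, ...) {
  cat("Two-component DNA-content mixture\n")
  cat(sprintf("  1N: weight %.3f, mean %.4g, sd %.3g\n", x$w1, x$mu1, x$sd1))
  cat(sprintf("  2N: weight %.3f, mean %.4g, sd %.3g\n", x$w2, x$mu2, x$sd2))
  cat(sprintf("  log-likelihood %.6g over %d events%s\n", x$loglik, x$n,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' @export
coef.dna_mixture_fit <- function(object, ...)
  c(w1 = object$w1, w2 = object$w2, mu1 = object$mu1, mu2 = object$mu2,
    sd1 = object$sd1, sd2 = object$sd2)

#' @export
plot.dna_mixture_fit <- function(x, fl1 = NULL, ...) {
  if (!is.null(fl1)) {
    graphics::hist(fl1, breaks = 60, freq = FALSE,
                   xlab = "DNA fluorescence (a.u.)", main = "", ...)
    xs <- seq(min(fl1), max(fl1), length.out = 400)
  } else {
    xs <- seq(x$mu1 - 4 * x$sd1, x$mu2 + 4 * x$sd2, length.out = 400)
    graphics::plot(NA, xlim = range(xs), ylim = c(0, 1.2 *
      max(x$w1 * stats::dnorm(x$mu1, x$mu1, x$sd1),
          x$w2 * stats::dnorm(x$mu2, x$mu2, x$sd2))),
      xlab = "DNA fluorescence (a.u.)", ylab = "density")
  }
  graphics::lines(xs, x$w1 * stats::dnorm(xs, x$mu1, x$sd1), col = "blue3")
  graphics::lines(xs, x$w2 * stats::dnorm(xs, x$mu2, x$sd2), col = "red3")
  invisible(x)
}

#' Subpopulation counts from a corrected total and a mixture fit
#'
#' Splits the clog-corrected absolute count between the 1N and 2N
#' components in proportion to the fitted mixture weights; the two counts
#' sum to the input exactly.
#'
#' @param c_s corrected absolute count, from [absolute_count()].
#' @param mix a [fit_dna_mixture()] result.
#' @return Named vector `c(n1 = , n2 = )`.
#' @export
subpopulation_counts <- function(c_s, mix) {
  stopifnot(inherits(mix, "dna_mixture_fit"), c_s >= 0)
  c(n1 = mix$w1 * c_s, n2 = mix$w2 * c_s)
}

#' Check the 2N-to-1N division bookkeeping over a time course
#'
#' Under the hypothesis that every division event is a replicated (2N)
#' cell splitting into two 1N daughters with no other flux, the 1N count
#' is fully determined by the drained 2N pool:
#' `n1_pred(t) = n1(0) + 2 (n2(0) - n2(t))`. The residuals
#' `n1_obs - n1_pred` measure how much of the observed count increase the
#' rule fails to explain; the series is judged consistent when the largest
#' residual stays within `tolerance` of the per-time total count.
#'
#' @param time time points, minutes.
#' @param n1,n2 observed 1N and 2N counts.
#' @param tolerance maximal |residual| as a fraction of the observed total
#'   at each time. Default 0.05.
#' @return A list with `residuals`, `n1_pred`, `consistent` (logical),
#'   `max_rel_residual`, and `n2_increase_flag` (`TRUE` when the 2N pool
#'   grows beyond tolerance, violating the drain-only hypothesis).
#' @export
check_2n_to_1n <- function(time, n1, n2, tolerance = 0.05) {
  stopifnot(length(time) >= 2L, length(n1) == length(time),
            length(n2) == length(time), all(is.finite(c(n1, n2))),
            tolerance > 0)
  n1_pred <- n1[1] + 2 * (n2[1] - n2)
  resid <- n1 - n1_pred
  total <- n1 + n2
  rel <- abs(resid) / pmax(total, .Machine$double.eps)
  n2_up <- max(n2 - n2[1]) > tolerance * total[1]
  list(time = time, n1_pred = n1_pred, residuals = resid,
       max_rel_residual = max(rel),
       consistent = max(rel) <= tolerance && !n2_up,
       n2_increase_flag = n2_up,
       tolerance = tolerance)
}
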