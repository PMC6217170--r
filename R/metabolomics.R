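#' Z-normalize an ion-intensity trace against a reference window
#'
#' Rescales raw ion counts to `Z = (S - mean_ref) / sd_ref`, where the
#' reference statistics come from a pre-perturbation window (typically the
#' first 5 minutes before pulsing begins, or 10 minutes for antibiotic
#' perturbation experiments). The transform is invariant to positive
#' affine rescaling of the raw intensities, so traces from different ions
#' and acquisitions become comparable.
#'
#' @param time time points, seconds (strictly increasing).
#' @param intensity raw ion counts (>= 0).
#' @param ref_window numeric length-2, `c(start, end)` of the reference
#'   window in seconds. Default `c(0, 300)`.
#' @return An object of class `"znorm_trace"`: list with `time`, `z`,
#'   `ref_mean`, `ref_sd`, `ref_window`.
#' @export
#' @examples
#' tt <- seq(0, 600, by = 10)
#' z_normalize(tt, 100 + (tt > 300) * 30 + 0 * tt, c(0, 300))
z_normalize <- function(time, intensity, ref_window = c(0, 300)) {
  stopifnot(length(time) == length(intensity), all(diff(time) > 0),
            all(is.finite(intensity)), all(intensity >= 0),
            length(ref_window) == 2L, ref_window[2] > ref_window[1])
  in_ref <- time >= ref_window[1] & time <= ref_window[2]
  if (sum(in_ref) < 3L) stop("need >= 3 points inside the reference window")
  m <- mean(intensity[in_ref])
  s <- stats::sd(intensity[in_ref])
  if (s == 0) stop("constant reference window: sd_ref = 0")
  structure(list(time = time, z = (intensity - m) / s,
                 ref_mean = m, ref_sd = s, ref_window = ref_window),
            class = "znorm_trace")
}

#' @export
print.znorm_trace <- function(x, ...) {
  cat(sprintf(
    "Z-normalized trace: %d points, reference [%g, %g] s (mean %.4g, sd %.4g)\n",
    length(x$z), x$ref_window[1], x$ref_window[2], x$ref_mean, x$ref_sd))
  invisible(x)
}

#' @export
plot.znorm_trace <- function(x, smooth_window = 5, ...) {
  graphics::plot(x$time, x$z, col = "grey60", xlab = "time (s)",
                 ylab = "Z-score", ...)
  graphics::lines(x$time, moving_average(x$z, smooth_window), col = "red3")
  invisible(x)
}

#' Centered moving-average smoothing
#'
#' Centered running mean with an odd window; at the edges the window
#' shrinks symmetrically so no points are dropped.
#'
#' @param x numeric vector.
#' @param window odd window length in points (>= 1). Default 5.
#' @return Smoothed vector, same length as `x`.
#' @export
moving_average <- function(x, window = 5L) {
  stopifnot(is.numeric(x), window >= 1L, window %% 2L == 1L)
  if (window == 1L) return(x)
  n <- length(x)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    mean(x[(i - h):(i + h)])
  }, numeric(1))
}

#' Per-pulse response features and trace classification
#'
#' For each glucose pulse, summarizes the Z-normalized response over the
#' interval to the next pulse: the peak Z-score, the time to peak, and the
#' return-to-baseline time (first post-peak time with `|z| < z_base`).
#' The trace is then classified by the morphology the pulses evoke:
#' \describe{
#'   \item{spike}{a sharp post-pulse transient (peak above `z_peak_min`)
#'     that returns to baseline before the next pulse — substrates and
#'     immediate catabolic intermediates.}
#'   \item{accumulate-deplete}{a sawtooth: Z rises steadily between pulses
#'     (strong positive Kendall rank trend) and drops right after the next
#'     pulse — pools consumed by the pulse-triggered synthesis burst.}
#'   \item{flat}{no pulse-locked structure.}
#' }
#' The per-trace label is the majority vote over pulse intervals.
#'
#' @param trace a [z_normalize()] result.
#' @param pulse_times pulse onset times, seconds; must lie within the
#'   trace and leave >= 10 samples per interval.
#' @param z_peak_min spike detection threshold on the peak Z. Default 3.
#' @param z_base baseline band half-width. Default 1.
#' @param trend_min minimum Kendall correlation for a rising inter-pulse
#'   trend. Default 0.5.
#' @return A list with `features` (data frame: pulse time, peak z, time to
#'   peak, return-to-baseline seconds, per-interval class) and `class`
#'   (trace-level label).
#' @export
pulse_response_features <- function(trace, pulse_times, z_peak_min = 3,
                                    z_base = 1, trend_min = 0.5) {
  stopifnot(inherits(trace, "znorm_trace"), length(pulse_times) >= 1L)
  tt <- trace$time; z <- trace$z
  if (any(pulse_times < tt[1]) || any(pulse_times > tt[length(tt)]))
    stop("pulse times fall outside the trace span")
  bounds <- c(sort(pulse_times), tt[length(tt)] + .Machine$double.eps)
  rows <- lapply(seq_along(pulse_times), function(i) {
    t0 <- bounds[i]; t1 <- bounds[i + 1L]
    sel <- tt >= t0 & tt < t1
    if (sum(sel) < 10L)
      stop("fewer than 10 samples between pulses at t = ", t0)
    ti <- tt[sel]; zi <- z[sel]
    ipk <- which.max(zi)
    peak <- zi[ipk]
    t_peak <- ti[ipk] - t0
    after <- seq_along(zi) > ipk & abs(zi) < z_base
    t_return <- if (any(after)) ti[which(after)[1]] - t0 else NA_real_
    tau <- suppressWarnings(stats::cor(ti, zi, method = "kendall"))
    drop_after <- if (i < length(pulse_times)) {
      nxt <- which(tt >= t1)[1]
      is.finite(peak) && !is.na(nxt) && tt[nxt] - t1 < (t1 - t0) / 4 &&
        z[min(nxt + 2L, length(z))] < peak / 2
    } else NA
    cls <- if (peak > z_peak_min && !is.na(t_return) &&
               t_return < (t1 - t0)) "spike"
    else if (!is.na(tau) && tau > trend_min && peak > z_base &&
             (is.na(drop_after) || drop_after)) "accumulate-deplete"
    else "flat"
    data.frame(pulse_time = t0, peak_z = peak, time_to_peak = t_peak,
               return_to_baseline = t_return, trend_tau = tau,
               class = cls, stringsAsFactors = FALSE)
  })
  feats <- do.call(rbind, rows)
  tab <- table(feats$class)
  list(features = feats, class = names(tab)[which.max(tab)])
}
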