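# Shared fixtures for the pulselag test suite.

ref_params <- function() ftsz_params_ref()

# random valid parameter set + a feedrate with a finite, non-trivial lag;
# used by the analytic/numeric equivalence and monotonicity properties
random_param_case <- function() {
  repeat {
    p <- ftsz_params(alpha0 = stats::runif(1, 0, 20),
                     alpha1 = stats::runif(1, 10, 500),
                     vmax = stats::runif(1, 5, 100),
                     km = stats::runif(1, 100, 5000),
                     z_threshold = stats::runif(1, 500, 5000),
                     z_init = 0)
    p <- update_params_test(p, z_init = stats::runif(1, 0, p$z_threshold * 0.95))
    fc <- critical_feedrate(p)
    f <- fc + stats::runif(1, 0.02, 2)
    lag <- lag_time_analytic(p, f)
    if (is.finite(lag) && lag > 1e-3 && lag < 1e5)
      return(list(params = p, f = f, lag = lag))
  }
}

# rebuild an ftsz_params with fields replaced (tests avoid reaching into
# package internals)
update_params_test <- function(p, ...) {
  fields <- unclass(p)
  upd <- list(...)
  fields[names(upd)] <- upd
  do.call(ftsz_params, fields)
}

# noise-free flat-then-linear OD series
make_od_series <- function(od_i = 0.30, t_lag = 200, mu = 5e-4,
                           duration = 500, dt = 5, noise_sd = 0,
                           seed = NULL) {
  tt <- seq(0, duration, by = dt)
  base <- od_i + mu * pmax(0, tt - t_lag)
  od <- if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    base + stats::rnorm(length(tt), 0, noise_sd)
  } else base
  list(time = tt, od = od)
}
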