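#' Read a model/fit configuration file
#'
#' YAML schema:
#' ```
#' model:
#'   alpha0: 5.0        # basal synthesis, copies/cell/min
#'   alpha1: 100.0      # feed-coupled gain (starting value; refit)
#'   vmax: 50.0         # max degradation, copies/cell/min
#'   km: 1000.0         # half-saturation abundance, copies/cell
#'   z_threshold: 2000.0
#'   z_init: 1000.0
#' fit:
#'   t_max_fit: 10000   # finite stand-in lag for non-dividing predictions
#'   exclude_zero_lag: true
#' ```
#' The `fit` block is optional; defaults are filled in.
#'
#' @param path path to a YAML file.
#' @return A list with elements `model` (an [ftsz_params()]) and `fit`
#'   (list with `t_max_fit`, `exclude_zero_lag`).
#' @export
read_pulselag_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$model))
    stop("config must contain a 'model' block")
  need <- c("alpha0", "alpha1", "vmax", "km", "z_threshold", "z_init")
  miss <- setdiff(need, names(raw$model))
  if (length(miss))
    stop("config model block is missing: ", paste(miss, collapse = ", "))
  model <- do.call(ftsz_params, raw$model[need])
  fit <- raw$fit
  if (is.null(fit)) fit <- list()
  if (is.null(fit$t_max_fit)) fit$t_max_fit <- 1e4
  if (is.null(fit$exclude_zero_lag)) fit$exclude_zero_lag <- TRUE
  list(model = model, fit = fit)
}

#' Write a configuration template
#'
#' @param params an [ftsz_params()] object.
#' @param path output YAML path.
#' @param t_max_fit,exclude_zero_lag fit block entries.
#' @return Invisibly, `path`.
#' @export
write_pulselag_config <- function(params, path, t_max_fit = 1e4,
                                  exclude_zero_lag = TRUE) {
  stopifnot(inherits(params, "ftsz_params"))
  yaml::write_yaml(list(model = unclass(params),
                        fit = list(t_max_fit = t_max_fit,
                                   exclude_zero_lag = exclude_zero_lag)),
                   path)
  invisible(path)
}
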