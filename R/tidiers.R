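#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted capture--recapture model
#'
#' One row per parameter with estimate, standard error and 95% Wald
#' interval, in the broom convention.
#'
#' @param x an `adcr_fit` from [fit_adcr()] or [fit_scr()].
#' @param ... unused.
#' @return a tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.adcr_fit <- function(x, ...) {
  x$ci
}

#' Glance at a fitted capture--recapture model
#'
#' @param x an `adcr_fit`.
#' @param ... unused.
#' @return a one-row tibble: `model`, `logLik`, `nobs` (individuals),
#'   `n_detections`, `npar`, `converged`, and the implied density
#'   `exp(rho)` per squared world unit.
#' @export
glance.adcr_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    logLik = x$loglik,
    nobs = x$data$n,
    n_detections = sum(x$data$Y),
    npar = length(x$par),
    converged = x$convergence,
    density = exp(x$par[["rho"]])
  )
}
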