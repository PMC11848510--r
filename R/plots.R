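#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a landscape layer
#'
#' @param object an [landscape()].
#' @param layer layer name or index.
#' @param ... unused.
#' @return a ggplot raster map of the covariate.
#' @export
autoplot.adcr_landscape <- function(object, layer = 1, ...) {
  cc <- cell_centers(object)
  nm <- if (is.numeric(layer)) names(object$layers)[layer] else layer
  ggplot2::ggplot(cc, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data[[nm]])) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = nm)
}

#' Plot a utilization distribution
#'
#' Raster map of the per-cell home-range mass with the activity centre
#' marked.
#'
#' @param object an `adcr_ud`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.adcr_ud <- function(object, ...) {
  df <- tibble::tibble(
    x = object$xll + (rep(seq_len(object$nx), object$ny) - 0.5) * object$h,
    y = object$yll + (rep(seq_len(object$ny),
                          each = object$nx) - 0.5) * object$h,
    mass = object$p
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$mass)) +
    ggplot2::geom_raster() +
    ggplot2::annotate("point", x = object$mu[1], y = object$mu[2],
                      shape = 4, colour = "red", size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "p*")
}

#' Coefficient plot of a fitted model
#'
#' Point estimates with 95% Wald intervals.
#'
#' @param object an `adcr_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.adcr_fit <- function(object, ...) {
  ggplot2::ggplot(object$ci,
                  ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::labs(x = "estimate", y = NULL, title = object$model)
}

#' True-versus-estimated scatter for an experiment
#'
#' One panel per parameter with the `y = x` reference line, the standard
#' visual check that estimates scatter around the truth.
#'
#' @param object an `adcr_experiment` from [run_experiment()].
#' @param estimator which estimator's parameters to plot.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.adcr_experiment <- function(object, estimator = "adcr", ...) {
  df <- dplyr::filter(object$params, .data$estimator == !!estimator,
                      is.finite(.data$true))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true, y = .data$est)) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo,
                                          ymax = .data$hi),
                             alpha = 0.6) +
    ggplot2::facet_wrap(~ .data$term, scales = "free") +
    ggplot2::labs(x = "true", y = "estimated", title = estimator)
}
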