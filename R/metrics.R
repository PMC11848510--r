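#' Overlap coefficient of two utilization distributions
#'
#' The volume of the overlapping region of two probability distributions on
#' the same grid: `sum over cells of min(p, q)`. Equals 1 iff the
#' distributions are identical, 0 iff their supports are disjoint.
#'
#' @param p,q `adcr_ud` objects on the same grid.
#' @return scalar in `[0, 1]`.
#' @export
overlap_coefficient <- function(p, q) {
  stopifnot(inherits(p, "adcr_ud"), inherits(q, "adcr_ud"))
  if (p$nx != q$nx || p$ny != q$ny || p$h != q$h) {
    stop("utilization distributions live on different grids")
  }
  sum(pmin(p$p, q$p))
}

## batch of home-range surfaces (n_cells x M) for any model object
homerange_surface_batch_ <- function(model, land, centers_x, centers_y) {
  if (inherits(model, "adcr_homerange_params")) {
    ud_batch_(land, model$gamma0, model$beta, centers_x, centers_y)
  } else if (inherits(model, "adcr_movement_params")) {
    ud_batch_(land, model$beta0 - model$alpha0, model$beta, centers_x,
              centers_y)
  } else if (inherits(model, "adcr_fit") && model$model == "adcr") {
    ud_batch_(land, model$par[["gamma0"]],
              model$par[grep("^beta", names(model$par))],
              centers_x, centers_y, model$scheme)
  } else if (inherits(model, "adcr_fit")) {
    pow <- if (model$mode == "euclidean") 2 else model$lcp_exponent
    g2 <- model$par[grep("^g2", names(model$par))]
    d <- scr_distance_matrix_(land, model$mode, g2, centers_x, centers_y,
                              seq_len(n_cells(land)))
    q <- exp(model$par[["g1"]] * d^pow)   # M x n_cells
    t(q / rowSums(q))
  } else {
    stop("unsupported model object for home-range surfaces")
  }
}

#' Mean home-range overlap over an activity-centre region
#'
#' Average of [overlap_coefficient()] between the true and fitted home
#' ranges over every cell-centre activity centre in a rectangular region
#' (by default the bounding box of the data's detector array, the
#' simulation study's `x, y = [9, 41]` window).
#'
#' @param true_model the true home-range model ([homerange_params()] or
#'   [movement_params()]).
#' @param fitted_model a fitted model (`adcr_fit` from [fit_adcr()] or
#'   [fit_scr()]), or another parameter set.
#' @param land the [landscape()].
#' @param region `c(xmin, xmax, ymin, ymax)` in world coordinates, or `NULL`
#'   for the detector bounding box of `fitted_model$data`.
#' @return scalar mean overlap.
#' @export
mean_overlap_over_array <- function(true_model, fitted_model, land,
                                    region = NULL) {
  if (is.null(region)) {
    if (!inherits(fitted_model, "adcr_fit")) {
      stop("region must be given when fitted_model carries no detector array")
    }
    pts <- fitted_model$data$detectors$points
    region <- c(range(pts$x), range(pts$y))
  }
  cc <- cell_centers(land)
  inside <- cc$x >= region[1] & cc$x <= region[2] &
    cc$y >= region[3] & cc$y <= region[4]
  if (!any(inside)) stop("no cell centres fall in the region")
  P <- homerange_surface_batch_(true_model, land, cc$x[inside], cc$y[inside])
  Q <- homerange_surface_batch_(fitted_model, land, cc$x[inside],
                                cc$y[inside])
  mean(colSums(pmin(P, Q)))
}

#' 90% highest-density area
#'
#' Home-range size measure: the area of the smallest set of cells (taken in
#' decreasing density order) whose cumulative mass reaches 0.9, times the
#' cell area `h^2`. A uniform distribution over 100 unit cells gives 90; a
#' point mass gives one cell.
#'
#' @param p an `adcr_ud`, or a bare numeric probability vector.
#' @param h cell side (taken from `p` when it is an `adcr_ud`).
#' @param level mass level (default 0.9).
#' @return area in squared world units.
#' @export
hda90 <- function(p, h = NULL, level = 0.9) {
  if (inherits(p, "adcr_ud")) {
    if (is.null(h)) h <- p$h
    p <- p$p
  }
  if (is.null(h)) h <- 1
  ps <- sort(p, decreasing = TRUE)
  k <- which(cumsum(ps) >= level * sum(ps))[1]
  k * h^2
}

#' Accuracy summary of estimates against truth
#'
#' Aggregates per-iteration records into the simulation study's accuracy
#' measures: `rmse = sqrt(mean((est - true)^2))`, `mbe = mean(est - true)`,
#' the Pearson correlation of `(true, est)`, and (when CI bounds are
#' present) the number of iterations whose 95% CI excludes zero.
#'
#' @param records a data frame with columns `true` and `est`, optionally
#'   `lo` and `hi` (CI bounds).
#' @return a one-row tibble: `n`, `rmse`, `mbe`, `pearson_r`,
#'   `ci_exclusion_count` (NA without CI columns); `pearson_r` is NA with
#'   fewer than 2 records or degenerate variance.
#' @export
accuracy_summary <- function(records) {
  stopifnot(is.data.frame(records), all(c("true", "est") %in% names(records)))
  ok <- is.finite(records$true) & is.finite(records$est)
  true <- records$true[ok]; est <- records$est[ok]
  err <- est - true
  r <- NA_real_
  if (length(true) >= 2 && stats::sd(true) > 0 && stats::sd(est) > 0) {
    r <- stats::cor(true, est)
  }
  ci_n <- NA_integer_
  if (all(c("lo", "hi") %in% names(records))) {
    lo <- records$lo[ok]; hi <- records$hi[ok]
    ci_n <- sum(lo > 0 | hi < 0, na.rm = TRUE)
  }
  tibble::tibble(
    n = length(err),
    rmse = if (length(err)) sqrt(mean(err^2)) else NA_real_,
    mbe = if (length(err)) mean(err) else NA_real_,
    pearson_r = r,
    ci_exclusion_count = ci_n
  )
}
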