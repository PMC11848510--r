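#' SCR parameter set
#'
#' Parameters of the comparison estimators: basic SCR has a Gaussian
#' detection function of Euclidean distance,
#' `ln(lambda_jk) = g0 + g1 ||s_j - mu||^2` with `g1 < 0`; the least-cost
#' path (LCP) variant replaces the Euclidean distance by the accumulated
#' least-cost distance `d_lcp(s_j, mu; g2)` whose per-edge log unit cost is
#' `g2 (z(s) + z(s'))/2` (a positive `g2` means the covariate increases
#' cost, i.e. the opposite sign convention to ADCR's permeability `beta`).
#' Internally `g1` is parameterized as `log(-g1)` so the optimizer works
#' unconstrained.
#'
#' @param rho log population density.
#' @param g0 log detectability at zero distance.
#' @param g1 distance coefficient, strictly negative.
#' @param g2 landscape-cost coefficient vector (LCP only; `NULL` otherwise).
#' @return an object of class `adcr_scr_params`.
#' @export
scr_params <- function(rho, g0, g1, g2 = NULL) {
  stopifnot(is.finite(rho), is.finite(g0), is.finite(g1), g1 < 0)
  structure(list(rho = rho, g0 = g0, g1 = g1,
                 g2 = if (is.null(g2)) NULL else as.numeric(g2)),
            class = "adcr_scr_params")
}

## 8-neighbour lattice edges of a landscape: from, to, length (h or sqrt(2) h)
lattice_edges8_ <- function(land) {
  nx <- land$nx; ny <- land$ny; h <- land$h
  ix <- rep(seq_len(nx), ny); iy <- rep(seq_len(ny), each = nx)
  cells <- seq_len(nx * ny)
  e <- function(mask, offset, len) {
    list(from = cells[mask], to = cells[mask] + offset,
         len = rep(len, sum(mask)))
  }
  parts <- list(
    e(ix < nx, 1L, h),                       # east
    e(iy < ny, nx, h),                       # north
    e(ix < nx & iy < ny, nx + 1L, sqrt(2) * h),  # north-east
    e(ix > 1L & iy < ny, nx - 1L, sqrt(2) * h)   # north-west
  )
  list(from = unlist(lapply(parts, `[[`, "from")),
       to = unlist(lapply(parts, `[[`, "to")),
       len = unlist(lapply(parts, `[[`, "len")))
}

#' Least-cost-path distances
#'
#' Dijkstra shortest-path cost between cells over the 8-neighbour lattice
#' graph. The cost of traversing the edge between adjacent cells `s`, `s'`
#' is `exp(g2 . (z(s) + z(s'))/2)` times the centre-to-centre length (`h` or
#' `sqrt(2) h`), so `g2 = 0` collapses to the octile lattice distance.
#' Distances are symmetric with `d(a, a) = 0`.
#'
#' @param land an [landscape()].
#' @param g2 cost coefficient(s), one per covariate layer.
#' @param sources,targets 1-based cell indices.
#' @return `length(sources)` x `length(targets)` matrix of distances.
#' @export
lcp_distances <- function(land, g2, sources, targets) {
  stopifnot(inherits(land, "adcr_landscape"))
  ed <- lattice_edges8_(land)
  Z <- covariate_matrix(land)
  g2 <- rep_len(as.numeric(g2), ncol(Z))
  zbar <- (Z[ed$from, , drop = FALSE] + Z[ed$to, , drop = FALSE]) / 2
  w <- exp(as.vector(zbar %*% g2)) * ed$len
  g <- igraph::make_empty_graph(n = n_cells(land), directed = FALSE)
  g <- igraph::add_edges(g, rbind(ed$from, ed$to))
  igraph::distances(g, v = sources, to = targets, weights = w,
                    algorithm = "dijkstra")
}

## distance matrix (centres x cells-of-interest) for a given mode
scr_distance_matrix_ <- function(land, mode, g2, centers_x, centers_y,
                                 cells, cache = NULL) {
  if (mode == "euclidean") {
    cc <- cell_centers(land)
    dx <- outer(centers_x, cc$x[cells], "-")
    dy <- outer(centers_y, cc$y[cells], "-")
    sqrt(dx^2 + dy^2)
  } else {
    key <- paste0("lcp|", paste(format(g2, digits = 17), collapse = ","),
                  "|", paste0(range(cells), collapse = ":"), "|",
                  length(cells))
    d <- cache_get_(cache, key)
    if (is.null(d)) {
      src <- coord_to_cell(land, centers_x, centers_y)
      d <- lcp_distances(land, g2, src, cells)
      cache_set_(cache, key, d)
    }
    d
  }
}

#' SCR full log-likelihood (Euclidean or least-cost path)
#'
#' Identical full-likelihood skeleton to [full_loglik()] -- the same
#' candidate-centre grid, Poisson count observation model and censoring
#' correction -- with the detection rate taken from the SCR detection
#' function instead of the PDE equilibrium:
#' `lambda_j(m) = exp(g0 + g1 d(s_j, m)^q)` where `d` is Euclidean
#' (`q = 2`) or the least-cost-path distance (`q = lcp_exponent`, default 1,
#' switchable to 2). With `normalize = TRUE` the detection surface is
#' rescaled to sum to one over the region (the utilization-distribution
#' convention of ADCR), which makes the Euclidean variant the exact
#' Gaussian-home-range counterpart of ADCR at `beta = 0`.
#'
#' @param params an [scr_params()].
#' @param data an [capture_data()].
#' @param land the [landscape()].
#' @param mode `"euclidean"` or `"lcp"`.
#' @param lcp_exponent exponent `q` on the LCP distance (1 or 2).
#' @param normalize normalize the home-range surface over the region
#'   (default `FALSE`, the conventional unnormalized detection function).
#' @param center_stride candidate-centre thinning as in [full_loglik()].
#' @param cache optional environment memoizing LCP distances per `g2`.
#' @return the log-likelihood.
#' @export
scr_loglik <- function(params, data, land, mode = c("euclidean", "lcp"),
                       lcp_exponent = 1, normalize = FALSE,
                       center_stride = 1, cache = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "adcr_scr_params"),
            inherits(data, "adcr_capture_data"))
  if (mode == "lcp" && is.null(params$g2)) stop("lcp mode requires g2")
  centers <- candidate_centers_(land, center_stride)
  dcells <- detector_cells_(data$detectors, land)
  pow <- if (mode == "euclidean") 2 else lcp_exponent
  if (normalize) {
    dall <- scr_distance_matrix_(land, mode, params$g2, centers$x, centers$y,
                                 seq_len(n_cells(land)), cache)
    q <- exp(params$g1 * dall^pow)           # M x n_cells
    pdet <- t(q[, dcells, drop = FALSE] / rowSums(q))
  } else {
    d <- scr_distance_matrix_(land, mode, params$g2, centers$x, centers$y,
                              dcells, cache)
    pdet <- t(exp(params$g1 * d^pow))        # J x M
  }
  Ysum <- counts_by_detector_(data)
  loglik_core_(pdet, a = (land$h * center_stride)^2,
               E = data$detectors$K * data$detectors$effort,
               Ysum = Ysum, lfact_y = sum(lfactorial(data$Y)),
               rho = params$rho, g0 = params$g0)
}

#' Fit basic SCR or SCR with least-cost path
#'
#' Quasi-Newton maximization of [scr_loglik()], sharing the machinery of
#' [fit_adcr()] (finite-difference gradients, observed-information standard
#' errors, Wald intervals, convergence flag). `g1` is optimized as
#' `log(-g1)`.
#'
#' @param data an [capture_data()].
#' @param land the [landscape()].
#' @param mode `"euclidean"` (basic SCR) or `"lcp"`.
#' @param init optional [scr_params()].
#' @param lcp_exponent,normalize,center_stride see [scr_loglik()].
#' @param hessian,control see [fit_adcr()].
#' @return an `adcr_fit` with model `"scr"` or `"scr_lcp"`; terms are
#'   reported on the natural scale (`g1`, not `log(-g1)`).
#' @export
fit_scr <- function(data, land, mode = c("euclidean", "lcp"), init = NULL,
                    lcp_exponent = 1, normalize = FALSE, center_stride = 1,
                    hessian = TRUE, control = list()) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "adcr_capture_data"), data$n > 0)
  n_g2 <- if (mode == "lcp") length(land$layers) else 0L
  if (is.null(init)) {
    mom <- moment_inits_(data, land)
    init <- scr_params(mom$rho, mom$g0_scr, mom$g1,
                       g2 = if (n_g2 > 0) rep(0, n_g2) else NULL)
  }
  par <- c(rho = init$rho, g0 = init$g0, lng1 = log(-init$g1))
  if (n_g2 > 0) {
    gn <- if (n_g2 == 1) "g2" else paste0("g2_", names(land$layers))
    par <- c(par, stats::setNames(rep_len(init$g2, n_g2), gn))
  }
  cache <- new.env(parent = emptyenv())
  negll <- function(p) {
    if (!all(is.finite(p)) || abs(p[3]) > 100) return(1e10)
    prm <- scr_params(p[1], p[2], -exp(p[3]),
                      g2 = if (n_g2 > 0) p[4:(3 + n_g2)] else NULL)
    ll <- suppressWarnings(
      scr_loglik(prm, data, land, mode = mode, lcp_exponent = lcp_exponent,
                 normalize = normalize, center_stride = center_stride,
                 cache = cache))
    if (!is.finite(ll)) 1e10 else -ll
  }
  fit <- run_fit_(par, negll, hessian, control,
                  model = if (mode == "lcp") "scr_lcp" else "scr",
                  data = data, land = land,
                  extra = list(mode = mode, lcp_exponent = lcp_exponent,
                               normalize = normalize,
                               center_stride = center_stride))
  ## report g1 on the natural scale (delta method for the SE)
  i <- which(names(fit$par) == "lng1")
  g1 <- -exp(fit$par[[i]])
  se_g1 <- abs(g1) * fit$se[i]
  fit$par[i] <- g1
  names(fit$par)[i] <- "g1"
  fit$se[i] <- se_g1
  fit$ci$term[i] <- "g1"
  fit$ci$estimate[i] <- g1
  fit$ci$std.error[i] <- se_g1
  fit$ci$conf.low[i] <- g1 - 1.96 * se_g1
  fit$ci$conf.high[i] <- g1 + 1.96 * se_g1
  fit
}

#' Model-implied home range of an SCR fit
#'
#' The normalized surface proportional to `exp(g1 d(s, mu)^q)` over the
#' region: the utilization distribution implied by the fitted detection
#' function, used for overlap and highest-density-area comparisons against
#' the true home range.
#'
#' @param fit an `adcr_fit` from [fit_scr()].
#' @param mu activity centre `(x, y)`.
#' @return an `adcr_ud`.
#' @export
scr_homerange <- function(fit, mu) {
  stopifnot(inherits(fit, "adcr_fit"), fit$model %in% c("scr", "scr_lcp"))
  land <- fit$landscape
  pow <- if (fit$mode == "euclidean") 2 else fit$lcp_exponent
  g2 <- fit$par[grep("^g2", names(fit$par))]
  d <- scr_distance_matrix_(land, fit$mode, g2, mu[1], mu[2],
                            seq_len(n_cells(land)))
  p <- exp(fit$par[["g1"]] * as.vector(d)^pow)
  new_ud_(p / sum(p), mu, land)
}
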