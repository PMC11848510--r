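#' Movement and home-range parameter sets
#'
#' `movement_params()` parameterizes the full movement process used by the
#' simulator: drift intensity `c = exp(alpha0)` toward the activity centre and
#' spatially varying permeability (diffusion coefficient)
#' `D(x, y) = exp(beta0 + beta . z(x, y))`, log-linear in the landscape
#' covariates. `homerange_params()` is the identifiable reparameterization
#' seen by the estimator: at equilibrium only the ratio `D/c` matters, so
#' `gamma0 = beta0 - alpha0` and unit drift enter. `exp(gamma0)` is the
#' home-range variance per axis in the homogeneous (`beta = 0`) Gaussian
#' limit.
#'
#' @param alpha0 log drift intensity (site fidelity); `c = exp(alpha0)`.
#' @param beta0 log-permeability intercept.
#' @param beta numeric vector of covariate coefficients, one per landscape
#'   layer (may be length 0 for a homogeneous landscape).
#' @param gamma0 `beta0 - alpha0`, the log ratio of diffusion to drift.
#' @return an object of class `adcr_movement_params` or
#'   `adcr_homerange_params`.
#' @export
movement_params <- function(alpha0, beta0, beta = numeric(0)) {
  stopifnot(is.finite(alpha0), is.finite(beta0), all(is.finite(beta)))
  structure(list(alpha0 = alpha0, beta0 = beta0, beta = as.numeric(beta)),
            class = "adcr_movement_params")
}

#' @rdname movement_params
#' @export
homerange_params <- function(gamma0, beta = numeric(0)) {
  stopifnot(is.finite(gamma0), all(is.finite(beta)))
  structure(list(gamma0 = gamma0, beta = as.numeric(beta)),
            class = "adcr_homerange_params")
}

## resolve any params object to (D vector over cells, drift intensity c)
resolve_movement_ <- function(land, params) {
  Z <- covariate_matrix(land)
  if (inherits(params, "adcr_movement_params")) {
    lin <- params$beta0
    cc <- exp(params$alpha0)
  } else if (inherits(params, "adcr_homerange_params")) {
    lin <- params$gamma0
    cc <- 1
  } else {
    stop("params must be movement_params() or homerange_params()")
  }
  lin <- rep(lin, nrow(Z))
  beta <- params$beta
  if (length(beta) > 0) {
    if (length(beta) != ncol(Z)) {
      stop(sprintf("beta has length %d but the landscape has %d layers",
                   length(beta), ncol(Z)))
    }
    lin <- lin + as.vector(Z %*% beta)
  }
  D <- exp(lin)
  if (!all(is.finite(D)) || any(D <= 0)) stop("non-finite or non-positive D")
  list(D = D, c = cc)
}

## Bernoulli function B(x) = x / (exp(x) - 1), numerically stable
bernoulli_fn_ <- function(x) {
  out <- x / expm1(x)
  small <- abs(x) < 1e-8
  out[small] <- 1 - x[small] / 2 + x[small]^2 / 12
  out[x < -700] <- -x[x < -700]  # expm1 -> -1 exactly; limit is -x
  out
}

## Interior faces of the grid: from-cell, to-cell (the +axis neighbour) and
## the +axis face-centre offset of the face, per axis.
face_table_ <- function(land) {
  nx <- land$nx; ny <- land$ny; h <- land$h
  ix <- rep(seq_len(nx), ny); iy <- rep(seq_len(ny), each = nx)
  cells <- seq_len(nx * ny)
  fx <- ix < nx
  fy <- iy < ny
  list(
    x = list(from = cells[fx], to = cells[fx] + 1L,
             face = land$xll + (ix[fx]) * h),     # x of face = left cell's east face
    y = list(from = cells[fy], to = cells[fy] + nx,
             face = land$yll + (iy[fy]) * h)
  )
}

## Directed edge rates for the generator: returns list(from, to, rate).
## Diffusion uses the TARGET cell's permeability (step-selection /
## conductance form): the jump rate into a cell scales with how permeable
## that cell is, so the drift-free equilibrium is proportional to D and home
## ranges skew toward permeable habitat.
## scheme "exp": exponentially fitted, rate(s->s') = D(s')/h^2 * B(-v_f h / D(s'))
## scheme "upwind": first-order upwind, rate(s->s') = D(s')/h^2 + max(+-v_f, 0)/h
edge_rates_ <- function(land, mu, D, cc, scheme = c("exp", "upwind")) {
  scheme <- match.arg(scheme)
  h <- land$h
  ft <- face_table_(land)
  from <- integer(0); to <- integer(0); rate <- numeric(0)
  for (ax in c("x", "y")) {
    f <- ft[[ax]]
    if (length(f$from) == 0L) next
    vf <- cc * (mu[[if (ax == "x") 1L else 2L]] - f$face)
    Dfrom <- D[f$from]; Dto <- D[f$to]
    if (scheme == "exp") {
      r_fwd <- Dto / h^2 * bernoulli_fn_(-vf * h / Dto)
      r_bwd <- Dfrom / h^2 * bernoulli_fn_(vf * h / Dfrom)
    } else {
      r_fwd <- Dto / h^2 + pmax(vf, 0) / h
      r_bwd <- Dfrom / h^2 + pmax(-vf, 0) / h
    }
    from <- c(from, f$from, f$to)
    to <- c(to, f$to, f$from)
    rate <- c(rate, r_fwd, r_bwd)
  }
  list(from = from, to = to, rate = rate)
}

#' Build the discrete advection--diffusion generator
#'
#' Assembles the sparse transition-rate (generator) matrix `Q` of the
#' continuous-time Markov chain that discretizes the advection--diffusion
#' equation on the landscape grid for one activity centre `mu`: diffusion in
#' step-selection (conductance) form -- the jump rate into a neighbouring
#' cell scales with the destination cell's permeability, `D(s')/h^2`, so
#' that the drift-free equilibrium is proportional to `D` and home ranges
#' skew toward permeable habitat -- advection as a conservative flux of the
#' drift field `v(s) = c (mu - s)` across cell faces, and zero-flux
#' reflecting boundaries. Face fluxes are exponentially fitted by default
#' (Scharfetter--Gummel weights `B(x) = x / (e^x - 1)`), which keeps all
#' off-diagonal rates non-negative and reproduces the Gaussian equilibrium of
#' the homogeneous landscape exactly at cell centres; plain first-order
#' upwind weighting is available for comparison. With [homerange_params()]
#' time is rescaled by `1/c`, so only `D/c = exp(gamma0 + beta . z)` and unit
#' drift enter.
#'
#' Rows of `Q` index the origin cell; every row sums to zero (probability is
#' conserved; nothing leaves the region), and only rook-adjacent couplings
#' are non-zero.
#'
#' @param land an [landscape()].
#' @param mu numeric length-2 activity centre `(x, y)` in world coordinates;
#'   must lie inside the landscape. Activity centres are taken at cell
#'   centres throughout the package.
#' @param params [movement_params()] or [homerange_params()].
#' @param scheme advection face weighting, `"exp"` (exponentially fitted,
#'   default) or `"upwind"`.
#' @return an object of class `adcr_generator`: list with the sparse `Q`
#'   (`Matrix::dgCMatrix`), `mu`, `D`, `c`, `scheme` and the landscape.
#' @examples
#' land <- landscape(matrix(0, 3, 3))
#' gen <- build_generator(land, mu = c(1.5, 1.5), homerange_params(0))
#' range(Matrix::rowSums(gen$Q))  # rows sum to zero
#' @export
build_generator <- function(land, mu, params, scheme = c("exp", "upwind")) {
  stopifnot(inherits(land, "adcr_landscape"), length(mu) == 2)
  scheme <- match.arg(scheme)
  if (mu[1] <= land$xll || mu[1] >= land$xll + land$nx * land$h ||
      mu[2] <= land$yll || mu[2] >= land$yll + land$ny * land$h) {
    stop("activity centre mu lies outside the landscape")
  }
  res <- resolve_movement_(land, params)
  n <- n_cells(land)
  er <- edge_rates_(land, mu, res$D, res$c, scheme)
  if (length(er$from) == 0L) {
    Q <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
  } else {
    Q <- Matrix::sparseMatrix(i = er$from, j = er$to, x = er$rate,
                              dims = c(n, n))
    Matrix::diag(Q) <- -Matrix::rowSums(Q)
  }
  structure(list(Q = Q, mu = as.numeric(mu), D = res$D, c = res$c,
                 scheme = scheme, landscape = land),
            class = "adcr_generator")
}

#' @export
print.adcr_generator <- function(x, ...) {
  cat(sprintf("<adcr_generator> %d cells, mu = (%g, %g), scheme = %s\n",
              nrow(x$Q), x$mu[1], x$mu[2], x$scheme))
  invisible(x)
}

new_ud_ <- function(p, mu, land) {
  structure(list(p = as.numeric(p), mu = as.numeric(mu),
                 nx = land$nx, ny = land$ny, h = land$h,
                 xll = land$xll, yll = land$yll),
            class = "adcr_ud")
}

#' @export
print.adcr_ud <- function(x, ...) {
  cat(sprintf(
    "<adcr_ud> %d x %d cells, mu = (%g, %g), sum = %.12f, max cell mass = %.4g\n",
    x$nx, x$ny, x$mu[1], x$mu[2], sum(x$p), max(x$p)))
  invisible(x)
}

#' @export
as.matrix.adcr_ud <- function(x, ...) matrix(x$p, x$nx, x$ny)

#' Equilibrium utilization distribution
#'
#' Solves the stationary system `p' Q = 0`, `sum(p) = 1` for the generator's
#' equilibrium distribution: the model's home range for the generator's
#' activity centre. One stationarity equation is replaced by the
#' normalization constraint and the system is solved by sparse LU; if that
#' fails (or the residual is out of tolerance) the smallest-singular-vector
#' of the dense operator is used as a fallback. The returned mass function is
#' non-negative, sums to one within 1e-10, and satisfies
#' `max |p' Q| <= 1e-8 * max|Q|`.
#'
#' @param gen an [build_generator()] result.
#' @return an object of class `adcr_ud` (fields `p`, `mu`, grid metadata).
#' @export
equilibrium_distribution <- function(gen) {
  stopifnot(inherits(gen, "adcr_generator"))
  n <- nrow(gen$Q)
  if (n == 1L) {
    return(new_ud_(1, gen$mu, gen$landscape))
  }
  A <- Matrix::t(gen$Q)
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  p <- tryCatch(as.numeric(Matrix::solve(A, b)), error = function(e) NULL)
  qmax <- max(abs(gen$Q@x), 0)
  bad <- is.null(p) || any(!is.finite(p)) ||
    max(abs(as.numeric(Matrix::crossprod(gen$Q, p)))) > 1e-8 * qmax * sum(abs(p))
  if (bad) {
    sv <- svd(as.matrix(Matrix::t(gen$Q)))
    p <- sv$v[, n]
    if (sum(p) < 0) p <- -p
  }
  p <- pmax(p, 0)
  p <- p / sum(p)
  resid <- max(abs(as.numeric(Matrix::crossprod(gen$Q, p))))
  if (resid > 1e-8 * qmax) {
    stop(sprintf("equilibrium solve failed: residual %.3g exceeds %.3g",
                 resid, 1e-8 * qmax))
  }
  new_ud_(p, gen$mu, gen$landscape)
}

#' Gaussian reference home range
#'
#' The closed-form home range of the homogeneous landscape: a bivariate
#' normal `N(mu, exp(gamma0) I)` evaluated at cell centres and renormalized
#' over the region. This is the exact equilibrium of the discrete operator
#' when `beta = 0` (with the default exponentially fitted scheme), and it is
#' the home-range surface implied by basic SCR's Gaussian detection function.
#' Centre evaluation (not cell integration) is used so that the discrete
#' identity with the PDE equilibrium is exact.
#'
#' @param mu activity centre `(x, y)`.
#' @param gamma0 log home-range variance; `gamma0 -> -Inf` degenerates to a
#'   point mass in the centre's cell.
#' @param land an [landscape()].
#' @return an `adcr_ud`.
#' @export
gaussian_reference <- function(mu, gamma0, land) {
  stopifnot(inherits(land, "adcr_landscape"), length(mu) == 2)
  cc <- cell_centers(land)
  d2 <- (cc$x - mu[1])^2 + (cc$y - mu[2])^2
  logp <- -d2 / (2 * exp(gamma0))
  logp <- logp - max(logp)
  p <- exp(logp)
  if (!any(p > 0) || !is.finite(exp(gamma0)) || exp(gamma0) == 0) {
    p <- as.numeric(d2 == min(d2))
  }
  new_ud_(p / sum(p), mu, land)
}
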