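#' Detector arrays
#'
#' Count detectors (e.g. camera traps with individual identification) at
#' fixed locations, surveyed over `K` occasions of constant effort. An
#' individual in a detector's grid cell is detected a Poisson number of
#' times per time step.
#'
#' `detector_array()` builds an array from coordinates;
#' `baseline_detectors()` lays out the simulation-study design: detectors at
#' the centres of every `spacing`-th cell from `margin` inward, which on the
#' 50 x 50 grid (margin 9, spacing 4) gives the 9 x 9 = 81 detectors
#' covering cells 9 to 41 on each axis.
#'
#' @param x,y detector world coordinates.
#' @param K number of occasions (default 1).
#' @param effort exposure per occasion, in time steps of the detection
#'   intensity (default 1): the per-occasion expected count at detector `j`
#'   is `effort * lambda_j`. Movement-simulation datasets pool `n_steps`
#'   per-step detection draws into one occasion, hence carry
#'   `effort = n_steps`.
#' @param id optional detector labels (default `1:J`).
#' @return an object of class `adcr_detectors`: a list with `points` (tibble
#'   `detector`, `x`, `y`), `K`, `effort` and `type = "count"`.
#' @export
detector_array <- function(x, y, K = 1, effort = 1, id = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 1, K >= 1, effort > 0)
  if (is.null(id)) id <- seq_along(x)
  structure(list(points = tibble::tibble(detector = id, x = x, y = y),
                 K = as.integer(K), effort = effort, type = "count"),
            class = "adcr_detectors")
}

#' @rdname detector_array
#' @param land an [landscape()] the array is placed on.
#' @param spacing cell spacing between detectors.
#' @param margin index of the first detector cell on each axis.
#' @export
baseline_detectors <- function(land, spacing = 4, margin = 9, K = 1,
                               effort = 1) {
  stopifnot(inherits(land, "adcr_landscape"))
  ix <- seq(margin, land$nx - margin + 1, by = spacing)
  iy <- seq(margin, land$ny - margin + 1, by = spacing)
  if (length(ix) == 0 || length(iy) == 0) stop("margin too large for the grid")
  g <- expand.grid(ix = ix, iy = iy)
  detector_array(x = land$xll + (g$ix - 0.5) * land$h,
                 y = land$yll + (g$iy - 0.5) * land$h, K = K,
                 effort = effort)
}

#' @export
print.adcr_detectors <- function(x, ...) {
  cat(sprintf("<adcr_detectors> %d count detectors, %d occasion(s)\n",
              nrow(x$points), x$K))
  invisible(x)
}

n_detectors <- function(det) nrow(det$points)

## map detectors to cells of a landscape (error if any fall outside)
detector_cells_ <- function(det, land) {
  coord_to_cell(land, det$points$x, det$points$y)
}

scheme_code_ <- function(scheme) match(scheme, c("exp", "upwind")) - 1L

#' One-step transition kernel of the explicit method
#'
#' Probability distribution over cells after time `dt` for an individual
#' starting as a point mass in `cell`, computed as the corresponding row of
#' `(I + delta Q)^substeps` with `delta = dt/substeps`: forward-Euler
#' (explicit-method) time stepping of the discretized advection--diffusion
#' equation. `substeps` defaults to the smallest count keeping every
#' substep transition probability non-negative (`1 + delta Q_ii >= 0`) with
#' a 10% margin; an explicitly supplied value that violates positivity is
#' refused with the required count in the message.
#'
#' @param gen an [build_generator()] result.
#' @param cell 1-based starting cell index.
#' @param dt elapsed time (one observation step is `dt = 1`).
#' @param substeps number of Euler substeps, or `NULL` for automatic.
#' @return numeric vector over cells; non-negative, sums to 1.
#' @export
step_kernel <- function(gen, cell, dt = 1, substeps = NULL) {
  stopifnot(inherits(gen, "adcr_generator"))
  n <- nrow(gen$Q)
  stopifnot(cell >= 1, cell <= n)
  v <- numeric(n)
  v[cell] <- 1
  if (dt == 0) return(v)
  maxout <- max(-Matrix::diag(gen$Q), 0)
  if (is.null(substeps)) {
    substeps <- max(1L, as.integer(ceiling(1.1 * dt * maxout)))
  } else {
    if (substeps < dt * maxout) {
      stop(sprintf(
        "substeps = %d violates positivity (1 + delta*Q_ii < 0); need >= %d",
        substeps, as.integer(ceiling(dt * maxout))))
    }
  }
  delta <- dt / substeps
  Qt <- Matrix::t(gen$Q)
  for (s in seq_len(substeps)) {
    v <- v + delta * as.numeric(Qt %*% v)
  }
  v
}

#' Simulate a movement track
#'
#' Forward-simulates one individual's path on the landscape grid: each unit
#' observation step is split into explicit-method substeps (see
#' [step_kernel()]) and the next cell is drawn from the categorical
#' substep distribution, which reproduces the explicit-method transition
#' kernel exactly at unit times. The first `burn_in` steps (which randomize
#' the initial location) are discarded.
#'
#' @param gen an [build_generator()] result.
#' @param start_cell 1-based starting cell (conventionally the activity
#'   centre's cell).
#' @param n_steps number of recorded steps.
#' @param burn_in discarded initial steps (default 0).
#' @param seed optional integer seed for reproducibility.
#' @return integer vector of `n_steps` 1-based cell indices.
#' @export
simulate_track <- function(gen, start_cell, n_steps, burn_in = 0, seed = NULL) {
  stopifnot(inherits(gen, "adcr_generator"), n_steps >= 1, burn_in >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  land <- gen$landscape
  as.integer(sim_tracks_cpp(land$nx, land$ny, land$h, land$xll, land$yll,
                            gen$D, gen$c, gen$mu[1], gen$mu[2],
                            as.integer(start_cell), as.integer(n_steps),
                            as.integer(burn_in), scheme_code_(gen$scheme),
                            1.1))
}

#' Simulate detections along a track
#'
#' At each time step spent in a cell containing a detector, the number of
#' detection events is Poisson with expectation `exp(g0)`; steps in cells
#' without a detector yield none. Counts are accumulated per detector over
#' the whole track (the single-occasion design of the simulation study), so
#' each detector's total is Poisson with mean `visits * exp(g0)`.
#'
#' @param track integer vector of cell indices ([simulate_track()]).
#' @param det an [detector_array()].
#' @param g0 log detectability.
#' @param land the [landscape()] the track lives on.
#' @return integer vector of detection counts, one per detector.
#' @export
simulate_detections <- function(track, det, g0, land) {
  stopifnot(inherits(det, "adcr_detectors"), inherits(land, "adcr_landscape"))
  dcells <- detector_cells_(det, land)
  J <- length(dcells)
  cell_to_det <- integer(n_cells(land))
  cell_to_det[dcells] <- seq_len(J)
  hits <- cell_to_det[track]
  visits <- tabulate(hits[hits > 0L], nbins = J)
  counts <- integer(J)
  active <- visits > 0L
  if (any(active) && is.finite(g0)) {
    counts[active] <- stats::rpois(sum(active), visits[active] * exp(g0))
  }
  counts
}

#' Simulation scenarios
#'
#' A scenario bundles everything needed to generate one capture--recapture
#' dataset from the movement model: the landscape (or a patch-generation
#' spec), the true parameters, the movement-simulation length and the
#' detector array. The baseline defaults follow the simulation study:
#' 50 x 50 grid with 5 random patches of 100--250 cells, `t = 5000` steps
#' after 100 burn-in steps, `g0 = -3`, `beta0 = 1`, and the 81-detector
#' array.
#'
#' @param rho log population density (expected `exp(rho)` activity centres
#'   per unit area).
#' @param alpha0 log drift intensity.
#' @param beta0 log-permeability intercept.
#' @param beta landscape coefficient(s) on permeability.
#' @param g0 log detectability.
#' @param n_steps,burn_in movement-simulation length (recorded/discarded).
#' @param land an [landscape()], or `NULL` to draw one per dataset from
#'   `patch_spec`.
#' @param patch_spec list of arguments to [generate_patch_landscape()]
#'   (used when `land` is `NULL`).
#' @param detectors an [detector_array()], or `NULL` for
#'   [baseline_detectors()] on the realized landscape.
#' @param detector_spec list of `spacing`, `margin`, `K` used to lay out the
#'   baseline array when `detectors` is `NULL`.
#' @param drop_low_permeability_detectors if `TRUE`, detectors in cells whose
#'   first covariate is below its landscape median (the non-patch background)
#'   are removed after the landscape is realized (the sparse-data design).
#' @return an object of class `adcr_scenario`.
#' @export
sim_scenario <- function(rho = -2, alpha0 = -0.5, beta0 = 1, beta = 0,
                         g0 = -3, n_steps = 5000, burn_in = 100,
                         land = NULL, patch_spec = list(nx = 50, ny = 50),
                         detectors = NULL,
                         detector_spec = list(spacing = 4, margin = 9, K = 1),
                         drop_low_permeability_detectors = FALSE) {
  stopifnot(n_steps > burn_in, burn_in >= 0)
  structure(list(rho = rho, alpha0 = alpha0, beta0 = beta0,
                 beta = as.numeric(beta), g0 = g0,
                 n_steps = as.integer(n_steps), burn_in = as.integer(burn_in),
                 land = land, patch_spec = patch_spec, detectors = detectors,
                 detector_spec = detector_spec,
                 drop_low_permeability_detectors =
                   isTRUE(drop_low_permeability_detectors)),
            class = "adcr_scenario")
}

#' Sparse-data scenario
#'
#' The supplemental design probing severe observation sparseness with a
#' detector layout biased toward one landscape element: detectability drops
#' to `g0 = -5`, the true parameters are fixed at `rho = -2`,
#' `alpha0 = -0.5`, `beta = 2`, `beta0 = 1`, and every detector lying in a
#' low-permeability (background, covariate -0.5) cell is removed from the
#' array. If the scenario carries a realized landscape the array is filtered
#' immediately (an error if no detector survives); with a patch spec the
#' filtering happens per generated dataset.
#'
#' @param base a baseline [sim_scenario()].
#' @return a modified `adcr_scenario`.
#' @export
sparse_scenario <- function(base) {
  stopifnot(inherits(base, "adcr_scenario"))
  out <- base
  out$g0 <- -5
  out$rho <- -2
  out$alpha0 <- -0.5
  out$beta <- 2
  out$beta0 <- 1
  out$drop_low_permeability_detectors <- TRUE
  if (!is.null(out$land)) {
    det <- out$detectors
    if (is.null(det)) det <- baseline_detectors(out$land)
    out$detectors <- filter_detectors_(det, out$land)
  }
  out
}

## drop detectors in below-median (background) cells of the first layer
filter_detectors_ <- function(det, land) {
  z <- as.vector(land$layers[[1]])
  cutoff <- stats::median(range(z))  # midpoint of binary values
  keep <- z[detector_cells_(det, land)] > cutoff
  if (!any(keep)) {
    stop("no detectors remain after removing low-permeability cells")
  }
  detector_array(det$points$x[keep], det$points$y[keep], K = det$K,
                 effort = det$effort, id = det$points$detector[keep])
}

#' Simulate a capture--recapture dataset
#'
#' The full data-generating process of the simulation study: realize the
#' landscape (if needed), draw the population size
#' `N ~ Poisson(exp(rho) * area)`, draw activity centres from the discrete
#' uniform distribution over cells, simulate every individual's movement
#' track, generate Poisson detections at co-located detectors, and censor
#' individuals never detected.
#'
#' @param scenario an [sim_scenario()].
#' @param seed optional integer seed (full dataset reproducible given
#'   scenario and seed).
#' @return a list with `data` (an [capture_data()] of the censored
#'   detections), `truth` (list: `N`, `centers` tibble, `tracks` matrix of
#'   cell indices `n_steps` x `N`, uncensored `counts`, true parameters,
#'   realized `land` and `detectors`) .
#' @export
simulate_dataset <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "adcr_scenario"))
  if (!is.null(seed)) withr::local_seed(seed)
  land <- scenario$land
  if (is.null(land)) {
    land <- do.call(generate_patch_landscape, scenario$patch_spec)
  }
  det <- scenario$detectors
  if (is.null(det)) {
    ds <- scenario$detector_spec
    det <- baseline_detectors(land, spacing = ds$spacing %||% 4,
                              margin = ds$margin %||% 9, K = ds$K %||% 1)
  }
  if (scenario$drop_low_permeability_detectors) {
    det <- filter_detectors_(land = land, det = det)
  }
  det$effort <- scenario$n_steps  # one pooled occasion of n_steps exposures
  mp <- movement_params(scenario$alpha0, scenario$beta0, scenario$beta)
  res <- resolve_movement_(land, mp)
  area <- n_cells(land) * land$h^2
  N <- stats::rpois(1, exp(scenario$rho) * area)
  cc <- cell_centers(land)
  J <- n_detectors(det)
  if (N == 0) {
    counts <- matrix(0L, 0, J)
    tracks <- matrix(0L, scenario$n_steps, 0)
    centers <- cc[0, c("cell", "x", "y")]
  } else {
    center_cells <- sample.int(n_cells(land), N, replace = TRUE)
    centers <- cc[center_cells, c("cell", "x", "y")]
    tracks <- sim_tracks_cpp(land$nx, land$ny, land$h, land$xll, land$yll,
                             res$D, res$c, centers$x, centers$y,
                             as.integer(center_cells),
                             scenario$n_steps, scenario$burn_in, 0L, 1.1)
    counts <- t(matrix(vapply(seq_len(N), function(i) {
      simulate_detections(tracks[, i], det, scenario$g0, land)
    }, integer(J)), nrow = J))
  }
  detected <- rowSums(counts) > 0
  data <- capture_data(counts[detected, , drop = FALSE], det)
  truth <- list(N = N, centers = centers, tracks = tracks, counts = counts,
                detected = detected,
                params = list(rho = scenario$rho, alpha0 = scenario$alpha0,
                              beta0 = scenario$beta0, beta = scenario$beta,
                              g0 = scenario$g0,
                              gamma0 = scenario$beta0 - scenario$alpha0),
                land = land, detectors = det)
  list(data = data, truth = truth)
}
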