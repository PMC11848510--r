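#' Raster landscape
#'
#' A rectangular grid of `nx` by `ny` square cells of side `h` carrying one or
#' more covariate layers. Cells are unit squares: cell `(i, j)` (1-based,
#' `i` running west to east, `j` south to north) has centre coordinates
#' `((i - 0.5) h, (j - 0.5) h)`, and the linear cell index is
#' `i + (j - 1) nx`. All distances between cells are centre-to-centre. This
#' single convention is shared by the PDE operator, the movement simulator and
#' the estimators.
#'
#' @param covariates a numeric `nx` by `ny` matrix, or a named list of such
#'   matrices (one per covariate layer).
#' @param h cell side length in world distance units (default 1).
#' @param xll,yll world coordinates of the lower-left corner of the grid
#'   (default 0); detector and capture coordinates are interpreted relative to
#'   the same origin.
#' @return an object of class `adcr_landscape` with fields `nx`, `ny`, `h`,
#'   `xll`, `yll` and `layers` (named list of matrices).
#' @examples
#' land <- landscape(matrix(0, 10, 10))
#' land
#' @export
landscape <- function(covariates, h = 1, xll = 0, yll = 0) {
  if (is.matrix(covariates)) covariates <- list(z = covariates)
  stopifnot(is.list(covariates), length(covariates) >= 1)
  if (is.null(names(covariates)) || any(names(covariates) == "")) {
    names(covariates) <- paste0("z", seq_along(covariates))
  }
  dims <- unique(lapply(covariates, dim))
  if (length(dims) != 1L) stop("all covariate layers must share dimensions")
  nx <- dims[[1]][1]; ny <- dims[[1]][2]
  if (nx < 1L || ny < 1L) stop("grid must have at least one cell per axis")
  if (!is.numeric(h) || length(h) != 1L || h <= 0) stop("h must be a positive scalar")
  for (l in covariates) {
    if (!all(is.finite(l))) stop("covariate layers must be finite everywhere")
  }
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), h = h,
         xll = xll, yll = yll, layers = covariates),
    class = "adcr_landscape"
  )
}

#' @export
print.adcr_landscape <- function(x, ...) {
  cat(sprintf("<adcr_landscape> %d x %d cells, h = %g, layers: %s\n",
              x$nx, x$ny, x$h, paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Cell centres of a landscape
#'
#' @param land an [landscape()] object.
#' @return a tibble with one row per cell: `cell` (linear index), `ix`, `iy`
#'   (1-based grid indices) and `x`, `y` (world coordinates of the centre),
#'   plus one column per covariate layer.
#' @export
cell_centers <- function(land) {
  stopifnot(inherits(land, "adcr_landscape"))
  ix <- rep(seq_len(land$nx), land$ny)
  iy <- rep(seq_len(land$ny), each = land$nx)
  out <- tibble::tibble(
    cell = seq_len(land$nx * land$ny),
    ix = ix, iy = iy,
    x = land$xll + (ix - 0.5) * land$h,
    y = land$yll + (iy - 0.5) * land$h
  )
  for (nm in names(land$layers)) out[[nm]] <- as.vector(land$layers[[nm]])
  out
}

n_cells <- function(land) land$nx * land$ny

## cells x layers covariate matrix
covariate_matrix <- function(land) {
  do.call(cbind, lapply(land$layers, as.vector))
}

## linear index from 1-based grid indices
cell_index <- function(land, ix, iy) ix + (iy - 1L) * land$nx

## world coordinate -> containing cell (error if outside)
coord_to_cell <- function(land, x, y) {
  ix <- floor((x - land$xll) / land$h) + 1L
  iy <- floor((y - land$yll) / land$h) + 1L
  ix <- pmin(pmax(ix, 1L), ifelse(x <= land$xll + land$nx * land$h, ix, NA))
  if (any(is.na(ix)) || any(ix < 1L | ix > land$nx | iy < 1L | iy > land$ny)) {
    stop("coordinates fall outside the landscape extent")
  }
  cell_index(land, as.integer(ix), as.integer(iy))
}

#' Generate a random patch landscape
#'
#' Binary-covariate landscapes for simulation studies: `n_patches` connected
#' patches are grown by seeded random accretion (each patch starts at a
#' uniformly drawn free cell and repeatedly annexes a uniformly chosen
#' 4-connected free neighbour until it reaches its target area). Patch cells
#' take `patch_value`, the background `background_value`. Placement that
#' cannot reach the target area is retried a bounded number of times and then
#' fails explicitly rather than silently truncating a patch.
#'
#' @param nx,ny grid dimensions (cells per axis).
#' @param n_patches number of patches (0 gives a uniform background).
#' @param area_range integer vector `c(min, max)`: per-patch area in cells is
#'   drawn uniformly from this range. Defaults to the baseline simulation
#'   setting of 5 patches of 100--250 cells on a 50 x 50 grid.
#' @param patch_value,background_value covariate values assigned to patch and
#'   non-patch cells (defaults 0.5 and -0.5).
#' @param h cell side length.
#' @param seed optional integer seed; the result is deterministic given the
#'   seed and does not disturb the caller's RNG stream.
#' @param max_tries placement retries per patch before failing.
#' @return an [landscape()] object with a single layer `z`.
#' @examples
#' land <- generate_patch_landscape(20, 20, n_patches = 2,
#'                                  area_range = c(10, 10), seed = 7)
#' sum(land$layers$z == 0.5)  # exactly 20 patch cells
#' @export
generate_patch_landscape <- function(nx, ny, n_patches = 5,
                                     area_range = c(100, 250),
                                     patch_value = 0.5, background_value = -0.5,
                                     h = 1, seed = NULL, max_tries = 100) {
  stopifnot(nx >= 2, ny >= 2, n_patches >= 0, length(area_range) == 2,
            all(area_range >= 1), area_range[1] <= area_range[2])
  if (n_patches * area_range[2] >= nx * ny) {
    stop("requested total patch area must be smaller than the grid")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  z <- matrix(background_value, nx, ny)
  occupied <- matrix(FALSE, nx, ny)
  if (n_patches > 0) {
    for (p in seq_len(n_patches)) {
      target <- if (area_range[1] == area_range[2]) area_range[1] else
        sample(seq(area_range[1], area_range[2]), 1L)
      placed <- FALSE
      ## block cells adjacent to earlier patches so each patch stays its own
      ## 4-connected component
      blocked <- occupied
      occ_cells <- which(occupied)
      if (length(occ_cells)) blocked[neighbors4_(occ_cells, nx, ny)] <- TRUE
      for (try in seq_len(max_tries)) {
        cells <- grow_patch_(blocked, nx, ny, target)
        if (!is.null(cells)) {
          occupied[cells] <- TRUE
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf("could not place patch %d of area %d after %d tries",
                     p, target, max_tries))
      }
    }
    z[occupied] <- patch_value
  }
  landscape(z, h = h)
}

## grow one 4-connected patch of `target` cells on free ground; NULL on failure
grow_patch_ <- function(occupied, nx, ny, target) {
  free <- which(!occupied)
  if (length(free) < target) return(NULL)
  start <- free[sample.int(length(free), 1L)]
  cells <- start
  in_patch <- rep(FALSE, nx * ny)
  in_patch[start] <- TRUE
  frontier <- neighbors4_(start, nx, ny)
  frontier <- frontier[!occupied[frontier] & !in_patch[frontier]]
  while (length(cells) < target) {
    if (length(frontier) == 0L) return(NULL)
    k <- frontier[sample.int(length(frontier), 1L)]
    cells <- c(cells, k)
    in_patch[k] <- TRUE
    nb <- neighbors4_(k, nx, ny)
    nb <- nb[!occupied[nb] & !in_patch[nb]]
    frontier <- unique(c(frontier[frontier != k], nb))
  }
  cells
}

## 4-neighbour linear indices of linear cell(s)
neighbors4_ <- function(cell, nx, ny) {
  i <- ((cell - 1L) %% nx) + 1L
  j <- ((cell - 1L) %/% nx) + 1L
  out <- c(
    ifelse(i > 1L, cell - 1L, NA_integer_),
    ifelse(i < nx, cell + 1L, NA_integer_),
    ifelse(j > 1L, cell - nx, NA_integer_),
    ifelse(j < ny, cell + nx, NA_integer_)
  )
  out[!is.na(out)]
}
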