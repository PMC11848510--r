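#' Read capture--recapture data from trap and capture files
#'
#' Whitespace-separated text in the style of spatial capture--recapture
#' software: a traps file with columns `detector ID, x, y` (world
#' coordinates) and a captures file with columns `session, individual,
#' occasion, detector, count`. Detectors are snapped to the landscape cell
#' containing their coordinates; individuals are ordered by first
#' appearance; duplicate `(individual, detector, occasion)` rows are summed
#' with a warning.
#'
#' @param traps_path,captures_path input files.
#' @param land the [landscape()] the coordinates refer to (detectors outside
#'   its extent are an error).
#' @param K number of occasions; default the largest occasion present.
#' @return an [capture_data()].
#' @export
read_capture_data <- function(traps_path, captures_path, land, K = NULL) {
  stopifnot(inherits(land, "adcr_landscape"))
  traps <- utils::read.table(traps_path, header = FALSE,
                             col.names = c("detector", "x", "y"),
                             colClasses = c("character", "numeric",
                                            "numeric"))
  if (anyDuplicated(traps$detector)) stop("detector IDs must be unique")
  caps <- utils::read.table(
    captures_path, header = FALSE,
    col.names = c("session", "individual", "occasion", "detector", "count"),
    colClasses = c("character", "character", "integer", "character",
                   "integer"))
  unknown <- setdiff(caps$detector, traps$detector)
  if (length(unknown)) {
    stop("captures reference unknown detectors: ",
         paste(unknown, collapse = ", "))
  }
  if (is.null(K)) K <- max(caps$occasion, 1L)
  if (any(caps$occasion < 1L | caps$occasion > K)) {
    stop("occasions must lie in [1, K]")
  }
  if (any(caps$count < 1L)) stop("capture counts must be >= 1")
  coord_to_cell(land, traps$x, traps$y)  # validates extent
  det <- detector_array(traps$x, traps$y, K = K, id = traps$detector)
  ids <- unique(caps$individual)
  J <- nrow(traps)
  Y <- array(0L, dim = c(length(ids), J, K))
  i <- match(caps$individual, ids)
  j <- match(caps$detector, traps$detector)
  k <- caps$occasion
  if (anyDuplicated(cbind(i, j, k))) {
    warning("duplicate (individual, detector, occasion) rows summed")
  }
  for (r in seq_along(i)) {
    Y[i[r], j[r], k[r]] <- Y[i[r], j[r], k[r]] + caps$count[r]
  }
  capture_data(Y, det, id = ids)
}

#' Write capture--recapture data as trap and capture files
#'
#' Inverse of [read_capture_data()]; only positive counts are written.
#'
#' @param data an [capture_data()].
#' @param traps_path,captures_path output files.
#' @param session session label (default 1).
#' @return invisibly, the two paths.
#' @export
write_capture_data <- function(data, traps_path, captures_path,
                               session = 1) {
  stopifnot(inherits(data, "adcr_capture_data"))
  pts <- data$detectors$points
  utils::write.table(
    data.frame(pts$detector, sprintf("%.17g", pts$x),
               sprintf("%.17g", pts$y)),
    traps_path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  long <- as_tibble(data)
  utils::write.table(
    data.frame(session, long$individual, long$occasion, long$detector,
               long$count),
    captures_path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(traps_path, captures_path))
}

#' Write / read a fitted model as JSON
#'
#' Lossless round trip of the estimation results: parameter estimates,
#' standard errors (missing values preserved as nulls), 95% Wald intervals,
#' log-likelihood, convergence flag, model tag and package version.
#'
#' @param fit an `adcr_fit`.
#' @param path JSON file.
#' @return `write_fit()` returns `path` invisibly; `read_fit()` returns a
#'   list with the stored fields (`par`, `se`, `ci`, `loglik`,
#'   `convergence`, `model`, `package_version`).
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "adcr_fit"))
  obj <- list(
    model = fit$model,
    package_version = as.character(utils::packageVersion("adcr")),
    parameters = as.list(fit$par),
    se = as.list(stats::setNames(fit$se, names(fit$par))),
    ci = fit$ci,
    loglik = fit$loglik,
    convergence = fit$convergence
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  raw <- jsonlite::fromJSON(path)
  list(
    model = raw$model,
    package_version = raw$package_version,
    par = unlist(raw$parameters),
    se = vapply(raw$se, function(v) if (is.null(v)) NA_real_ else v,
                numeric(1)),
    ci = tibble::as_tibble(lapply(raw$ci, function(col) {
      if (is.list(col)) {
        vapply(col, function(v) if (is.null(v)) NA else v, col[[1]][1])
      } else col
    })),
    loglik = raw$loglik,
    convergence = raw$convergence
  )
}
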