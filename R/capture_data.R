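#' Capture--recapture data from count detectors
#'
#' Detection counts `Y[i, j, k]` for detected individual `i` at detector `j`
#' on occasion `k`. Only detected individuals are retained (each must have at
#' least one detection); the censoring of never-detected individuals is part
#' of the observation process and is accounted for in the likelihood.
#'
#' @param counts an `n x J` integer matrix (single occasion) or `n x J x K`
#'   array of non-negative detection counts.
#' @param detectors the [detector_array()] the counts refer to; its `K` must
#'   match the array's third dimension.
#' @param id optional individual labels.
#' @return an object of class `adcr_capture_data` with fields `Y`
#'   (`n x J x K` array), `detectors`, `n`, `id`.
#' @export
capture_data <- function(counts, detectors, id = NULL) {
  stopifnot(inherits(detectors, "adcr_detectors"))
  if (length(dim(counts)) == 2) {
    counts <- array(counts, dim = c(nrow(counts), ncol(counts), 1L))
  }
  stopifnot(length(dim(counts)) == 3)
  n <- dim(counts)[1]
  if (dim(counts)[2] != n_detectors(detectors)) {
    stop("counts and detector array disagree on the number of detectors")
  }
  if (dim(counts)[3] != detectors$K) {
    stop(sprintf("counts have %d occasions but the detector array has K = %d",
                 dim(counts)[3], detectors$K))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("detection counts must be non-negative integers")
  }
  if (n > 0 && any(apply(counts, 1, sum) < 1)) {
    stop("every retained individual must have at least one detection")
  }
  if (is.null(id)) id <- seq_len(n)
  structure(list(Y = counts, detectors = detectors, n = n, id = id),
            class = "adcr_capture_data")
}

#' @export
print.adcr_capture_data <- function(x, ...) {
  cat(sprintf(
    "<adcr_capture_data> %d individuals, %d detectors, %d occasion(s), %d detections\n",
    x$n, n_detectors(x$detectors), x$detectors$K, sum(x$Y)))
  invisible(x)
}

#' @export
as_tibble.adcr_capture_data <- function(x, ...) {
  d <- dim(x$Y)
  idx <- which(x$Y > 0, arr.ind = TRUE)
  tibble::tibble(
    individual = x$id[idx[, 1]],
    detector = x$detectors$points$detector[idx[, 2]],
    occasion = as.integer(idx[, 3]),
    count = as.integer(x$Y[idx])
  ) |> dplyr::arrange(.data$individual, .data$occasion, .data$detector)
}

## per-individual counts summed over occasions: n x J
counts_by_detector_ <- function(data) {
  if (dim(data$Y)[3] == 1L) {
    matrix(data$Y, dim(data$Y)[1], dim(data$Y)[2])
  } else {
    apply(data$Y, c(1, 2), sum)
  }
}
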