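#' Read a raster layer into a landscape
#'
#' Reads either an ESRI ASCII grid (header lines `ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize` and optional `NODATA_value`, then
#' `nrows` whitespace-separated data rows, first row northernmost) or a
#' headerless numeric matrix (rows also north-up, `cellsize` taken as 1).
#' The north-up file row order maps to grid index `iy = nrows - row + 1`, so
#' the first data row fills `iy = ny` (see [landscape()] for the cell
#' convention). NODATA values inside the domain are an error: the domain must
#' be fully covered.
#'
#' @param path file to read.
#' @return a single-layer [landscape()]; `h` is the file's `cellsize`.
#' @seealso [write_raster()]
#' @export
read_raster <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty raster file: ", path)
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  is_esri <- length(first) == 2L && is.na(suppressWarnings(as.numeric(first[1])))
  if (is_esri) {
    hdr <- list()
    i <- 1L
    while (i <= length(lines)) {
      parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(parts) == 2L && is.na(suppressWarnings(as.numeric(parts[1])))) {
        hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
        i <- i + 1L
      } else break
    }
    for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
      if (is.null(hdr[[key]]) || is.na(hdr[[key]])) {
        stop("malformed ESRI ASCII header: missing ", key)
      }
    }
    ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
    data_lines <- lines[seq(i, length.out = length(lines) - i + 1L)]
    vals <- as.numeric(unlist(strsplit(trimws(data_lines), "\\s+")))
    if (anyNA(vals)) stop("non-numeric data in raster body")
    if (length(vals) != ncols * nrows) {
      stop(sprintf("raster body has %d values, header promises %d x %d = %d",
                   length(vals), ncols, nrows, ncols * nrows))
    }
    if (!is.null(hdr$nodata_value) && any(vals == hdr$nodata_value)) {
      stop("NODATA values inside the domain are not supported")
    }
    m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
    z <- t(m[rev(seq_len(nrows)), , drop = FALSE])  # -> [ix, iy], iy northward
    landscape(z, h = hdr$cellsize, xll = hdr$xllcorner, yll = hdr$yllcorner)
  } else {
    m <- tryCatch(as.matrix(utils::read.table(path)),
                  error = function(e) stop("malformed raster matrix: ",
                                           conditionMessage(e)))
    if (anyNA(m)) stop("non-numeric data in raster body")
    z <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
    landscape(unname(z), h = 1)
  }
}

#' Write a landscape layer as an ESRI ASCII grid
#'
#' Inverse of [read_raster()]: values are written north-up at full double
#' precision (17 significant digits), so a write-read round trip reproduces
#' the layer to better than 1e-12 relative error.
#'
#' @param land an [landscape()] object.
#' @param path output file.
#' @param layer layer name or index to write (default the first).
#' @return `path`, invisibly.
#' @export
write_raster <- function(land, path, layer = 1) {
  stopifnot(inherits(land, "adcr_landscape"))
  z <- land$layers[[layer]]
  if (is.null(z)) stop("no such layer: ", layer)
  hdr <- c(
    sprintf("ncols %d", land$nx),
    sprintf("nrows %d", land$ny),
    sprintf("xllcorner %.17g", land$xll),
    sprintf("yllcorner %.17g", land$yll),
    sprintf("cellsize %.17g", land$h),
    "NODATA_value -9999"
  )
  rows <- vapply(rev(seq_len(land$ny)), function(iy) {
    paste(sprintf("%.17g", z[, iy]), collapse = " ")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
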