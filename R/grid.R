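#' Define a regular analysis grid
#'
#' A `grid_spec` describes a regular, axis-aligned raster grid on a projected
#' coordinate system: the number of rows and columns, the coordinates of the
#' lower-left corner, and the (square) cell size. Grid layers are stored as
#' plain R matrices with row 1 at the *top* (northernmost) edge, the usual
#' raster orientation.
#'
#' Cell ownership follows the half-open convention: a cell owns
#' `[x0, x0 + cellsize) x [y0, y0 + cellsize)`, i.e. its left and bottom
#' edges. Points on the extreme top or right edge of the grid fall outside it.
#'
#' @param nrow,ncol positive integer grid dimensions.
#' @param xmin,ymin coordinates of the lower-left grid corner.
#' @param cellsize side length of a (square) cell, in the same units as
#'   `xmin`/`ymin` (e.g. 5000 for a 5 km analysis grid).
#' @return An object of class `grid_spec`.
#' @examples
#' gs <- grid_spec(20, 20, cellsize = 5000)
#' cell_centers(gs)[1:3, ]
#' @export
grid_spec <- function(nrow, ncol, xmin = 0, ymin = 0, cellsize = 1) {
  stopifnot(
    length(nrow) == 1, length(ncol) == 1, nrow >= 1, ncol >= 1,
    nrow == as.integer(nrow), ncol == as.integer(ncol),
    is.finite(xmin), is.finite(ymin), cellsize > 0
  )
  structure(
    list(
      nrow = as.integer(nrow), ncol = as.integer(ncol),
      xmin = as.numeric(xmin), ymin = as.numeric(ymin),
      cellsize = as.numeric(cellsize)
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells, cell size %g, origin (%g, %g)\n",
    x$nrow, x$ncol, x$cellsize, x$xmin, x$ymin
  ))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d@%g+(%g,%g)", x$nrow, x$ncol, x$cellsize, x$xmin, x$ymin)
}

n_cells <- function(spec) spec$nrow * spec$ncol

grid_ymax <- function(spec) spec$ymin + spec$nrow * spec$cellsize
grid_xmax <- function(spec) spec$xmin + spec$ncol * spec$cellsize

same_grid <- function(a, b, tol = 1e-9) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

stop_if_grid_mismatch <- function(a, b, what = "grids") {
  if (!same_grid(a, b)) {
    stop(sprintf("%s are on different grid specifications (%s vs %s)",
                 what, format(a), format(b)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Cell centre coordinates of a grid
#'
#' @param spec a [grid_spec()].
#' @return A two-column matrix (`x`, `y`) with one row per cell, in R's
#'   column-major matrix order (cell id = linear matrix index).
#' @export
cell_centers <- function(spec) {
  col <- rep(seq_len(spec$ncol), each = spec$nrow)
  row <- rep(seq_len(spec$nrow), times = spec$ncol)
  cbind(
    x = spec$xmin + (col - 0.5) * spec$cellsize,
    y = grid_ymax(spec) - (row - 0.5) * spec$cellsize
  )
}

#' Locate points on a grid
#'
#' Maps point coordinates to linear cell indices under the half-open cell
#' convention (cells own their left and bottom edges). Points outside the
#' grid map to `NA`.
#'
#' @param spec a [grid_spec()].
#' @param x,y numeric coordinate vectors of equal length.
#' @return Integer vector of linear cell indices (into an `nrow x ncol`
#'   matrix), `NA` for points off the grid.
#' @export
xy_to_cell <- function(spec, x, y) {
  stopifnot(length(x) == length(y))
  col <- floor((x - spec$xmin) / spec$cellsize) + 1
  # rows count from the top; bottom-closed intervals in y
  row <- spec$nrow - floor((y - spec$ymin) / spec$cellsize)
  ok <- col >= 1 & col <= spec$ncol & row >= 1 & row <= spec$nrow &
    is.finite(x) & is.finite(y)
  idx <- rep(NA_integer_, length(x))
  idx[ok] <- as.integer((col[ok] - 1) * spec$nrow + row[ok])
  idx
}

empty_layer <- function(spec, fill = NA_real_) {
  matrix(fill, nrow = spec$nrow, ncol = spec$ncol)
}

#' Write a grid layer as an ESRI ASCII raster
#'
#' Plain-text `.asc` export (ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value header followed by rows from north to south), readable by any
#' GIS. `NA` cells are written as the nodata value.
#'
#' @param layer numeric matrix on `spec` (row 1 = north).
#' @param spec a [grid_spec()].
#' @param path output file path.
#' @param nodata nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(layer, spec, path, nodata = -9999) {
  stopifnot(is.matrix(layer), nrow(layer) == spec$nrow, ncol(layer) == spec$ncol)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", spec$ncol),
    sprintf("nrows %d", spec$nrow),
    sprintf("xllcorner %.10g", spec$xmin),
    sprintf("yllcorner %.10g", spec$ymin),
    sprintf("cellsize %.10g", spec$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  vals <- layer
  vals[is.na(vals)] <- nodata
  writeLines(apply(vals, 1, function(r) paste(format(r, digits = 10, trim = TRUE, scientific = FALSE), collapse = " ")), con)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path path to a `.asc` file written by [write_ascii_grid()] or any
#'   GIS exporting the standard six-line header.
#' @return A list with `layer` (matrix, `NA` where nodata) and `spec`
#'   (a [grid_spec()]).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ESRI ASCII header in ", path, call. = FALSE)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols) {
    stop("ESRI ASCII body does not match declared dimensions", call. = FALSE)
  }
  layer <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  layer[layer == nodata] <- NA_real_
  list(
    layer = layer,
    spec = grid_spec(hdr$nrows, hdr$ncols, hdr$xllcorner, hdr$yllcorner,
                     hdr$cellsize)
  )
}
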