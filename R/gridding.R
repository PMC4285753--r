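#' Per-species presence cells on the analysis grid
#'
#' An `occurrence_set` stores the deduplicated presence cells of one species
#' (at most one entry per grid cell) together with the pre-deduplication
#' record tally per cell, kept for diagnostics only.
#'
#' @param species species label.
#' @param cells integer vector of distinct linear cell indices.
#' @param counts integer vector of raw record counts per cell (same length
#'   as `cells`; defaults to 1 each).
#' @param spec the [grid_spec()] the cells index into.
#' @param n_skipped number of records dropped for falling off the grid.
#' @return An `occurrence_set`.
#' @export
occurrence_set <- function(species, cells, counts = NULL, spec,
                           n_skipped = 0L) {
  cells <- as.integer(cells)
  if (anyDuplicated(cells)) {
    stop("occurrence cells must be unique (one entry per cell)",
         call. = FALSE)
  }
  if (length(cells) && (min(cells) < 1 || max(cells) > n_cells(spec))) {
    stop("occurrence cell index out of grid bounds", call. = FALSE)
  }
  if (is.null(counts)) counts <- rep(1L, length(cells))
  stopifnot(length(counts) == length(cells), all(counts >= 1))
  structure(
    list(species = species, cells = cells, counts = as.integer(counts),
         spec = spec, n_skipped = as.integer(n_skipped)),
    class = "occurrence_set"
  )
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf(
    "<occurrence_set> '%s': %d presence cells (%d records, %d skipped)\n",
    x$species, length(x$cells), sum(x$counts), x$n_skipped
  ))
  invisible(x)
}

#' Aggregate point records to presence cells
#'
#' Bins sighting records onto the analysis grid and collapses duplicates so
#' each species has at most one presence entry per cell, the standard
#' treatment for opportunistic recording-scheme data. Records falling
#' outside the grid are skipped with a warning and counted in `n_skipped`.
#'
#' @param records data.frame with columns `species`, `x`, `y` (coordinates
#'   in the grid's CRS; sub-cell record precision is ignored and records are
#'   treated as points).
#' @param spec the analysis [grid_spec()].
#' @return Named list of [occurrence_set()] objects, one per species.
#' @export
aggregate_occurrences <- function(records, spec) {
  stopifnot(is.data.frame(records),
            all(c("species", "x", "y") %in% names(records)))
  idx <- xy_to_cell(spec, records$x, records$y)
  off <- is.na(idx)
  if (any(off)) {
    warning(sum(off), " record(s) outside grid bounds were skipped",
            call. = FALSE)
  }
  out <- list()
  for (sp in unique(as.character(records$species))) {
    sel <- records$species == sp & !off
    tab <- table(idx[sel])
    cells <- as.integer(names(tab))
    ord <- order(cells)
    out[[sp]] <- occurrence_set(
      species = sp, cells = cells[ord], counts = as.integer(tab)[ord],
      spec = spec, n_skipped = sum(records$species == sp & off)
    )
  }
  out
}

#' Allocate tetrad crop extents to the analysis grid
#'
#' Splits each source cell's ("tetrad", typically 2 x 2 km) mapped extent
#' among the analysis-grid cells it overlaps, proportionally to overlap
#' area, and sums contributions per analysis cell. Total hectares are
#' conserved exactly for tetrads lying inside the grid; the part of a
#' tetrad overhanging the grid edge is clipped (as when a source cell
#' straddles a coastline mask), so only the on-grid share is allocated.
#'
#' @param tetrads data.frame with columns `x0`, `y0` (lower-left corner),
#'   `size` (side length) and `ha` (mapped extent, hectares).
#' @param spec the analysis [grid_spec()].
#' @return Matrix of hectares per analysis cell (an extent grid).
#' @export
allocate_extent <- function(tetrads, spec) {
  stopifnot(is.data.frame(tetrads),
            all(c("x0", "y0", "size", "ha") %in% names(tetrads)))
  if (any(tetrads$size <= 0)) stop("zero-area tetrad", call. = FALSE)
  if (any(tetrads$ha < 0)) stop("negative tetrad extent", call. = FALSE)
  out <- matrix(0, spec$nrow, spec$ncol)
  cs <- spec$cellsize
  ymax <- grid_ymax(spec)
  for (i in seq_len(nrow(tetrads))) {
    tx0 <- tetrads$x0[i]; ty0 <- tetrads$y0[i]
    tx1 <- tx0 + tetrads$size[i]; ty1 <- ty0 + tetrads$size[i]
    area <- tetrads$size[i]^2
    c0 <- max(1L, floor((tx0 - spec$xmin) / cs) + 1L)
    c1 <- min(spec$ncol, ceiling((tx1 - spec$xmin) / cs))
    r0 <- max(1L, spec$nrow - ceiling((ty1 - spec$ymin) / cs) + 1L)
    r1 <- min(spec$nrow, spec$nrow - floor((ty0 - spec$ymin) / cs))
    if (c0 > c1 || r0 > r1) next
    for (cc in c0:c1) {
      gx0 <- spec$xmin + (cc - 1) * cs
      ox <- min(tx1, gx0 + cs) - max(tx0, gx0)
      if (ox <= 0) next
      for (rr in r0:r1) {
        gy1 <- ymax - (rr - 1) * cs
        oy <- min(ty1, gy1) - max(ty0, gy1 - cs)
        if (oy <= 0) next
        out[rr, cc] <- out[rr, cc] + tetrads$ha[i] * (ox * oy) / area
      }
    }
  }
  out
}

#' Bilinear regridding between regular grids
#'
#' Interpolates a coarse-grid layer at the cell centres of a finer grid
#' using bilinear interpolation between the four surrounding coarse cell
#' centres. Fine cells whose centre falls outside the hull of coarse cell
#' centres take the value of the nearest in-hull position (clamped
#' coordinates); the number of such cells is returned in the
#' `"n_extrapolated"` attribute. Missing coarse values propagate to any
#' fine cell whose interpolation stencil touches them.
#'
#' @param layer matrix on `coarse_spec`.
#' @param coarse_spec,fine_spec [grid_spec()] objects; the coarse grid must
#'   cover the fine grid's extent.
#' @return Matrix on `fine_spec` with attribute `n_extrapolated`.
#' @export
regrid_bilinear <- function(layer, coarse_spec, fine_spec) {
  stopifnot(is.matrix(layer), nrow(layer) == coarse_spec$nrow,
            ncol(layer) == coarse_spec$ncol)
  if (coarse_spec$xmin > fine_spec$xmin ||
      coarse_spec$ymin > fine_spec$ymin ||
      grid_xmax(coarse_spec) < grid_xmax(fine_spec) ||
      grid_ymax(coarse_spec) < grid_ymax(fine_spec)) {
    stop("coarse grid does not cover the fine grid extent", call. = FALSE)
  }
  ctr <- cell_centers(fine_spec)
  cs <- coarse_spec$cellsize
  # fractional column/row positions in coarse cell-centre coordinates
  u <- (ctr[, "x"] - (coarse_spec$xmin + cs / 2)) / cs       # 0-based col
  v <- ((grid_ymax(coarse_spec) - cs / 2) - ctr[, "y"]) / cs # 0-based row
  n_extrap <- sum(u < 0 | u > coarse_spec$ncol - 1 |
                    v < 0 | v > coarse_spec$nrow - 1)
  u <- pmin(pmax(u, 0), coarse_spec$ncol - 1)
  v <- pmin(pmax(v, 0), coarse_spec$nrow - 1)
  c0 <- pmin(floor(u), coarse_spec$ncol - 2); c0 <- pmax(c0, 0)
  r0 <- pmin(floor(v), coarse_spec$nrow - 2); r0 <- pmax(r0, 0)
  du <- u - c0
  dv <- v - r0
  at <- function(r, c) layer[cbind(r + 1, c + 1)]
  vals <- (1 - du) * (1 - dv) * at(r0, c0) +
    du * (1 - dv) * at(r0, c0 + 1) +
    (1 - du) * dv * at(r0 + 1, c0) +
    du * dv * at(r0 + 1, c0 + 1)
  out <- matrix(vals, fine_spec$nrow, fine_spec$ncol)
  attr(out, "n_extrapolated") <- n_extrap
  out
}
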