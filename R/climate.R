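#' Monthly climate stack
#'
#' Bundles twelve months of minimum temperature, maximum temperature and
#' precipitation on one grid, the raw input from which all bioclimatic
#' predictors are derived. Temperatures are in degrees Celsius, precipitation
#' in millimetres per month.
#'
#' @param tmin,tmax,prec numeric arrays of dimension `c(nrow, ncol, 12)`
#'   (months January..December in slice order).
#' @param spec the [grid_spec()] all layers share.
#' @param period free-text period label (e.g. `"present"`, `"future"`).
#' @return An object of class `monthly_climate`.
#' @details Validation enforces `tmax >= tmin` cell-wise, non-negative
#'   precipitation, and a common missing-data mask across all 36 layers
#'   (a cell is valid only if every month of every variable is non-missing).
#' @export
monthly_climate <- function(tmin, tmax, prec, spec, period = "present") {
  for (nm in c("tmin", "tmax", "prec")) {
    a <- get(nm)
    if (!is.array(a) || length(dim(a)) != 3 || dim(a)[3] != 12) {
      stop(nm, " must be an nrow x ncol x 12 array", call. = FALSE)
    }
    if (dim(a)[1] != spec$nrow || dim(a)[2] != spec$ncol) {
      stop(nm, " dimensions do not match the grid spec", call. = FALSE)
    }
  }
  mask <- apply(!is.na(tmin) & !is.na(tmax) & !is.na(prec), c(1, 2), all)
  per_var_mask <- function(a) apply(!is.na(a), c(1, 2), any)
  if (!isTRUE(all.equal(per_var_mask(tmin), per_var_mask(prec))) ||
      !isTRUE(all.equal(per_var_mask(tmin), per_var_mask(tmax)))) {
    stop("tmin, tmax and prec must share one missing-data mask", call. = FALSE)
  }
  viol <- tmax < tmin
  if (any(viol, na.rm = TRUE)) {
    stop(sprintf("tmax < tmin at %d cell-months", sum(viol, na.rm = TRUE)),
         call. = FALSE)
  }
  if (any(prec < 0, na.rm = TRUE)) {
    stop("negative precipitation", call. = FALSE)
  }
  structure(
    list(tmin = tmin, tmax = tmax, prec = prec, spec = spec,
         period = period, mask = mask),
    class = "monthly_climate"
  )
}

#' @export
print.monthly_climate <- function(x, ...) {
  cat(sprintf("<monthly_climate> period '%s' on %s (%d valid cells)\n",
              x$period, format(x$spec), sum(x$mask)))
  invisible(x)
}

#' Predictor stack
#'
#' A named collection of derived environmental layers (Bio01..Bio19, GDD5,
#' or any user-supplied grids) sharing one grid and validity mask; the
#' environmental space the distribution models are fitted in.
#'
#' @param layers named list of numeric matrices, all `nrow x ncol`.
#' @param spec the common [grid_spec()].
#' @param mask optional logical validity matrix; defaults to cells that are
#'   non-missing in every layer.
#' @return An object of class `predictor_stack`.
#' @export
predictor_stack <- function(layers, spec, mask = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1)
  nms <- names(layers)
  if (is.null(nms) || anyNA(nms) || any(nms == "") || anyDuplicated(nms)) {
    stop("layers must have unique non-empty names", call. = FALSE)
  }
  for (nm in nms) {
    l <- layers[[nm]]
    if (!is.matrix(l) || nrow(l) != spec$nrow || ncol(l) != spec$ncol) {
      stop("layer '", nm, "' does not match the grid spec", call. = FALSE)
    }
  }
  if (is.null(mask)) {
    mask <- Reduce(`&`, lapply(layers, function(l) !is.na(l)))
  }
  stopifnot(is.matrix(mask), nrow(mask) == spec$nrow, ncol(mask) == spec$ncol)
  structure(list(layers = layers, spec = spec, mask = mask),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("<predictor_stack> %d layers on %s: %s\n",
              length(x$layers), format(x$spec),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' @export
`[.predictor_stack` <- function(x, i) {
  predictor_stack(x$layers[i], x$spec, x$mask)
}

#' Flatten a predictor stack to a cells-by-variables matrix
#'
#' @param stack a [predictor_stack()].
#' @param cells optional integer vector of linear cell indices; defaults to
#'   all valid (masked-in) cells.
#' @param vars optional character vector of layer names to keep, in order.
#' @return Numeric matrix with one row per cell and one named column per
#'   layer; the row's cell index is in `rownames`.
#' @export
stack_matrix <- function(stack, cells = NULL, vars = NULL) {
  if (is.null(vars)) vars <- names(stack$layers)
  missing_vars <- setdiff(vars, names(stack$layers))
  if (length(missing_vars)) {
    stop("layers not in stack: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cells)) cells <- which(stack$mask)
  out <- vapply(vars, function(v) stack$layers[[v]][cells],
                numeric(length(cells)))
  out <- matrix(out, nrow = length(cells), ncol = length(vars),
                dimnames = list(as.character(cells), vars))
  out
}
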