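#' Multivariate environmental similarity surface (MESS)
#'
#' Measures how similar each projection cell's climate is to a set of
#' reference points, per variable, and takes the minimum over variables as
#' the cell's MESS. For a variable with reference minimum `min`, maximum
#' `max` and `f` = percentage of reference values strictly below the
#' projection value `p`, the similarity is
#' \itemize{
#'   \item `100 * (p - min) / (max - min)` if `f = 0`,
#'   \item `2 f` if `0 < f <= 50`,
#'   \item `2 (100 - f)` if `50 < f < 100`,
#'   \item `100 * (max - p) / (max - min)` if `f = 100`.
#' }
#' Negative values flag conditions outside the reference range (novel
#' climate); 100 means a value at the reference median, not novel at all.
#' The most dissimilar variable (MoD) is the variable attaining the
#' minimum, with ties resolved to the first variable in the reference's
#' column order.
#'
#' @param reference numeric matrix of reference conditions (rows = training
#'   points, named columns = variables).
#' @param projection a [predictor_stack()] (or numeric matrix with the same
#'   columns) holding the conditions to assess.
#' @return A `mess_result`: `mess` (grid matrix or vector), `mod`
#'   (integer-coded variable index, same shape, with `levels` attribute),
#'   `variables`, `reference_summary` (per-variable min/max/n), and
#'   `flagged_constant` (variables whose reference range is degenerate:
#'   their similarity is 100 where the projection equals the constant and 0
#'   elsewhere).
#' @export
mess <- function(reference, projection) {
  reference <- as.matrix(reference)
  vars <- colnames(reference)
  if (is.null(vars)) stop("reference needs named columns", call. = FALSE)
  as_grid <- inherits(projection, "predictor_stack")
  if (as_grid) {
    cells <- which(projection$mask)
    P <- stack_matrix(projection, cells, vars)
  } else {
    P <- as.matrix(projection)[, vars, drop = FALSE]
  }
  reference <- reference[stats::complete.cases(reference), , drop = FALSE]
  nref <- nrow(reference)
  if (nref < 1) stop("empty reference set", call. = FALSE)

  sim <- matrix(NA_real_, nrow(P), length(vars),
                dimnames = list(NULL, vars))
  flagged <- character()
  for (v in vars) {
    rv <- sort(reference[, v])
    mn <- rv[1]
    mx <- rv[nref]
    p <- P[, v]
    if (mx == mn) {
      flagged <- c(flagged, v)
      sim[, v] <- ifelse(p == mn, 100, 0)
      next
    }
    # f: percentage of reference values strictly below p
    f <- 100 * findInterval(p, rv, left.open = TRUE) / nref
    s <- ifelse(f == 0, 100 * (p - mn) / (mx - mn),
         ifelse(f <= 50, 2 * f,
         ifelse(f < 100, 2 * (100 - f),
                100 * (mx - p) / (mx - mn))))
    sim[, v] <- s
  }
  mess_v <- do.call(pmin, as.data.frame(sim))
  mod_v <- max.col(-sim, ties.method = "first")

  if (as_grid) {
    spec <- projection$spec
    mg <- empty_layer(spec); mg[cells] <- mess_v
    dg <- matrix(NA_integer_, spec$nrow, spec$ncol); dg[cells] <- mod_v
  } else {
    mg <- mess_v
    dg <- mod_v
  }
  attr(dg, "levels") <- vars
  structure(
    list(
      mess = mg, mod = dg, variables = vars,
      reference_summary = data.frame(
        variable = vars,
        min = apply(reference, 2, min),
        max = apply(reference, 2, max),
        n = nref, row.names = NULL
      ),
      flagged_constant = flagged
    ),
    class = "mess_result"
  )
}

#' @export
print.mess_result <- function(x, ...) {
  m <- x$mess[!is.na(x$mess)]
  cat(sprintf(
    "<mess_result> %d cells over %d variables; MESS range [%.1f, %.1f]; %.1f%% novel (MESS < 0)\n",
    length(m), length(x$variables), min(m), max(m), 100 * mean(m < 0)
  ))
  invisible(x)
}

#' Area share of the most dissimilar variable
#'
#' Summarizes a MESS result as the percentage of (masked-in) area for which
#' each variable is the most dissimilar one. With `within_range = TRUE`
#' cells where no variable leaves its reference range (MESS >= 0) are
#' reported as a separate `"within-range"` class, mirroring the grey class
#' of a MoD map; otherwise every cell is attributed to its minimizing
#' variable regardless of sign.
#'
#' @param mess_result a [mess()] result computed on a predictor stack.
#' @param mask optional logical matrix restricting the area.
#' @param within_range report non-novel cells as their own class?
#' @return data.frame `category`, `n_cells`, `share_pct` (shares sum to
#'   100).
#' @export
mod_summary <- function(mess_result, mask = NULL, within_range = TRUE) {
  stopifnot(inherits(mess_result, "mess_result"))
  m <- mess_result$mess
  d <- mess_result$mod
  sel <- !is.na(m)
  if (!is.null(mask)) sel <- sel & mask
  if (!any(sel)) stop("empty area mask", call. = FALSE)
  vars <- mess_result$variables
  cat_v <- vars[d[sel]]
  if (within_range) cat_v[m[sel] >= 0] <- "within-range"
  lev <- c(if (within_range) "within-range", vars)
  tab <- table(factor(cat_v, levels = lev))
  data.frame(
    category = names(tab),
    n_cells = as.integer(tab),
    share_pct = 100 * as.integer(tab) / sum(tab),
    row.names = NULL
  )
}
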