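#' Jolliffe's principal-component variable rejection, method B2
#'
#' Reduces a candidate predictor set to a low-collinearity subset. The
#' procedure runs PCA on the correlation matrix of the retained variables;
#' every component whose eigenvalue falls below `lambda0` is taken in
#' ascending eigenvalue order and, for each, the not-yet-rejected variable
#' with the largest absolute loading on that component is discarded. PCA is
#' then recomputed on the survivors and the cycle repeats until every
#' eigenvalue is at least `lambda0` (or only one variable remains). Ties in
#' absolute loading are broken by variable name order so the result is
#' deterministic. Zero-variance variables are rejected up-front and flagged.
#'
#' @param x numeric matrix or data.frame, rows = observations (grid cells),
#'   columns = candidate variables (named).
#' @param lambda0 eigenvalue threshold below which a component triggers a
#'   rejection (default 0.70).
#' @return A list of class `selection_result` with `retained`, `rejected`
#'   (data.frame: variable, round, eigenvalue of the triggering component),
#'   `eigenvalues` (of the final retained set), `lambda0` and
#'   `zero_variance` (variables discarded before PCA).
#' @export
jolliffe_b2 <- function(x, lambda0 = 0.70) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (ncol(x) < 2) stop("need at least two candidate variables", call. = FALSE)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < ncol(x) + 1) {
    stop("need at least variables + 1 complete rows", call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  zero_var <- colnames(x)[sds == 0]
  retained <- setdiff(colnames(x), zero_var)
  rejected <- data.frame(variable = character(), round = integer(),
                         eigenvalue = numeric(), stringsAsFactors = FALSE)
  round_i <- 0L
  repeat {
    if (length(retained) < 2) break
    eg <- eigen(stats::cor(x[, retained, drop = FALSE]), symmetric = TRUE)
    if (all(eg$values >= lambda0)) break
    round_i <- round_i + 1L
    low <- which(eg$values < lambda0)
    low <- low[order(eg$values[low])]        # smallest eigenvalue first
    dropped <- character()
    for (k in low) {
      load <- abs(eg$vectors[, k])
      names(load) <- retained
      load <- load[setdiff(retained, dropped)]
      if (!length(load)) next
      # max |loading|, ties by variable name order
      cand <- names(load)[load == max(load)]
      victim <- sort(cand)[1]
      dropped <- c(dropped, victim)
      rejected <- rbind(rejected, data.frame(
        variable = victim, round = round_i, eigenvalue = eg$values[k],
        stringsAsFactors = FALSE
      ))
    }
    retained <- setdiff(retained, dropped)
  }
  final_eval <- if (length(retained) >= 2) {
    eigen(stats::cor(x[, retained, drop = FALSE]), symmetric = TRUE,
          only.values = TRUE)$values
  } else {
    rep(1, length(retained))
  }
  structure(
    list(retained = retained, rejected = rejected,
         eigenvalues = final_eval, lambda0 = lambda0,
         zero_variance = zero_var),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> B2, lambda0 = %g\n", x$lambda0))
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$rejected)) {
    cat("  rejected:", paste(x$rejected$variable, collapse = ", "), "\n")
  }
  if (length(x$zero_variance)) {
    cat("  zero-variance:", paste(x$zero_variance, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pairwise Pearson correlation matrix
#'
#' Thin wrapper over [stats::cor()] that flags zero-variance columns (their
#' correlations are undefined and returned as `NA`).
#'
#' @param x numeric matrix or data.frame (columns = variables).
#' @return Symmetric correlation matrix with unit diagonal; attribute
#'   `"undefined"` lists zero-variance variables, if any.
#' @export
pearson_matrix <- function(x) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  undef <- colnames(x)[sds == 0]
  r <- suppressWarnings(stats::cor(x))
  diag(r) <- 1
  if (length(undef)) attr(r, "undefined") <- undef
  r
}
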