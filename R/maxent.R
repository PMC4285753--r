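#' Maxent model configuration
#'
#' Settings for the presence-only maximum-entropy fit. Feature classes can
#' be fixed or chosen automatically from the presence sample size, mirroring
#' the usual Maxent defaults at desk scale: fewer than 10 presences use
#' linear features only, 10-79 add quadratic, and 80 or more add hinge
#' features.
#'
#' @param classes `"auto"` or a subset of `c("linear", "quadratic",
#'   "hinge")`.
#' @param n_knots hinge knots per variable per direction (default 50).
#' @param background_n background cells sampled uniformly from the valid
#'   mask (all cells are used if fewer are available).
#' @param reg_multiplier global multiplier on the regularization weights
#'   (1 = defaults; 0 = unpenalized maximum likelihood).
#' @param max_iter,tol optimizer budget: iteration cap and relative
#'   objective-change convergence tolerance. A fit that exhausts the cap is
#'   returned with a diagnostic warning rather than an error: the iterate is
#'   a usable (slightly under-converged) solution, and aborting a whole
#'   resampling job on one slow fold would be worse.
#' @return A `maxent_config` list.
#' @export
maxent_config <- function(classes = "auto", n_knots = 50L,
                          background_n = 10000L, reg_multiplier = 1,
                          max_iter = 500L, tol = 1e-6) {
  if (!identical(classes, "auto")) {
    stopifnot(all(classes %in% c("linear", "quadratic", "hinge")),
              length(classes) >= 1)
  }
  structure(list(classes = classes, n_knots = as.integer(n_knots),
                 background_n = as.integer(background_n),
                 reg_multiplier = reg_multiplier,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "maxent_config")
}

auto_classes <- function(n_presence) {
  if (n_presence < 10) "linear"
  else if (n_presence < 80) c("linear", "quadratic")
  else c("linear", "quadratic", "hinge")
}

# Regularization level for linear/quadratic features as a function of the
# presence sample size (log-linear interpolation through the conventional
# Maxent schedule); hinge features use a flat 0.5.
beta_lq <- function(m) {
  pts_m <- c(10, 30, 100)
  pts_b <- c(1.0, 0.2, 0.05)
  if (m <= pts_m[1]) return(pts_b[1])
  if (m >= pts_m[3]) return(pts_b[3])
  stats::approx(log(pts_m), pts_b, xout = log(m))$y
}

#' Build Maxent feature expansions
#'
#' Expands normalized predictors (each in `[0, 1]`) into the requested
#' feature classes. Linear features are the identity, quadratic the square,
#' and hinge features are the pairs `max(0, (x - k)/(1 - k))` (forward) and
#' `max(0, (k - x)/k)` (reverse) at evenly spaced knots, so every feature
#' is again bounded in `[0, 1]`.
#'
#' @param xnorm numeric matrix of normalized predictors (rows = cells,
#'   named columns).
#' @param classes subset of `c("linear", "quadratic", "hinge")`.
#' @param n_knots hinge knots per variable per direction.
#' @return List with `F` (feature matrix) and `meta` (data.frame `class`,
#'   `var`, `knot`, `dir` describing each column).
#' @export
maxent_features <- function(xnorm, classes, n_knots = 50L) {
  stopifnot(is.matrix(xnorm), !is.null(colnames(xnorm)))
  vars <- colnames(xnorm)
  cols <- list()
  meta <- list()
  add <- function(values, class, var, knot = NA_real_, dir = NA_character_) {
    cols[[length(cols) + 1L]] <<- values
    meta[[length(meta) + 1L]] <<- data.frame(
      class = class, var = var, knot = knot, dir = dir,
      stringsAsFactors = FALSE
    )
  }
  for (v in vars) {
    x <- xnorm[, v]
    if ("linear" %in% classes) add(x, "linear", v)
    if ("quadratic" %in% classes) add(x * x, "quadratic", v)
    if ("hinge" %in% classes) {
      fwd <- seq(0, 1 - 1 / n_knots, length.out = n_knots)
      rev <- seq(1 / n_knots, 1, length.out = n_knots)
      for (k in fwd) add(pmax(0, (x - k) / (1 - k)), "hinge", v, k, "fwd")
      for (k in rev) add(pmax(0, (k - x) / k), "hinge", v, k, "rev")
    }
  }
  F <- do.call(cbind, cols)
  meta <- do.call(rbind, meta)
  colnames(F) <- paste0(meta$class, ":", meta$var,
                        ifelse(is.na(meta$knot), "",
                               paste0(":", meta$dir, ":",
                                      formatC(meta$knot, format = "g"))))
  list(F = F, meta = meta)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Core optimizer: minimizes
#   logsumexp(F_bg w) - mean(F_pr w) + sum(lambda * |w|)
# by accelerated proximal gradient (FISTA) with backtracking line search and
# restart on non-monotone steps. Convex; features bounded in [0, 1].
fit_maxent_weights <- function(F_pr, F_bg, lambda,
                               tol = 1e-6, max_iter = 500L) {
  nf <- ncol(F_bg)
  stopifnot(ncol(F_pr) == nf, length(lambda) == nf, all(lambda >= 0))
  fbar <- colMeans(F_pr)
  smooth_obj <- function(w) {
    eta <- drop(F_bg %*% w)
    logsumexp(eta) - sum(fbar * w)
  }
  grad_at <- function(w) {
    eta <- drop(F_bg %*% w)
    lse <- logsumexp(eta)
    q <- exp(eta - lse)
    list(g = drop(crossprod(F_bg, q)) - fbar, f = lse - sum(fbar * w))
  }
  soft <- function(u, t) sign(u) * pmax(abs(u) - t, 0)

  w <- numeric(nf)
  y <- w
  tk <- 1
  L <- 1
  obj_old <- smooth_obj(w) + sum(lambda * abs(w))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    gy <- grad_at(y)
    repeat {
      w_new <- soft(y - gy$g / L, lambda / L)
      dw <- w_new - y
      f_new <- smooth_obj(w_new)
      if (f_new <= gy$f + sum(gy$g * dw) + (L / 2) * sum(dw * dw) + 1e-12) {
        break
      }
      L <- L * 2
    }
    obj_new <- f_new + sum(lambda * abs(w_new))
    if (obj_new > obj_old) {       # restart momentum on overshoot
      tk <- 1
      y <- w
      obj_trial <- obj_new
      gy <- grad_at(y)
      w_new <- soft(y - gy$g / L, lambda / L)
      obj_new <- smooth_obj(w_new) + sum(lambda * abs(w_new))
      if (obj_new > obj_old) {     # cannot improve: accept previous iterate
        w_new <- w
        obj_new <- obj_old
      }
    }
    t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- w_new + ((tk - 1) / t_next) * (w_new - w)
    tk <- t_next
    w <- w_new
    if (abs(obj_old - obj_new) / max(1, abs(obj_new)) < tol) {
      converged <- TRUE
      obj_old <- obj_new
      break
    }
    obj_old <- obj_new
    L <- max(L / 2, 1e-3)          # allow the step size to grow back
  }
  eta_bg <- drop(F_bg %*% w)
  logZ <- logsumexp(eta_bg)
  q <- exp(eta_bg - logZ)
  entropy <- -sum(ifelse(q > 0, q * log(q), 0))
  list(weights = w, objective = obj_old, converged = converged,
       n_iter = iter, q = q, logZ = logZ, entropy = entropy)
}

#' Fit a presence-only maximum-entropy distribution model
#'
#' Fits the Gibbs distribution over background cells whose feature
#' expectations match the presence sample, with L1 regularization
#' (per-feature weights `beta_class * sd(feature at presences) /
#' sqrt(n_presences)`, hinge beta 0.5 and a sample-size schedule for
#' linear/quadratic). Predictors are normalized to `[0, 1]` by their
#' background range and clamped outside it. The logistic output is
#' `p = c q(x) / (1 + c q(x))` with `q` the raw (background-normalized)
#' Gibbs density and `c = exp(H)` the exponential entropy of the fitted
#' distribution, so a cell with "typical" suitability maps to p = 0.5.
#'
#' @param predictors a [predictor_stack()].
#' @param presence_cells integer linear cell indices of the presences.
#' @param background_cells integer cell indices to use as background; if
#'   `NULL`, `config$background_n` cells are sampled uniformly from the
#'   valid mask (seeded by the caller).
#' @param vars predictor layer names to use (default: all).
#' @param config a [maxent_config()].
#' @return A `maxent_model`: feature metadata, fitted weights,
#'   normalization bounds, background cells, `logZ`, `entropy`, and the
#'   convergence record.
#' @seealso [predict.maxent_model()], [resample_fit()]
#' @export
fit_maxent <- function(predictors, presence_cells, background_cells = NULL,
                       vars = NULL, config = maxent_config()) {
  stopifnot(inherits(predictors, "predictor_stack"))
  if (is.null(vars)) vars <- names(predictors$layers)
  presence_cells <- as.integer(presence_cells)
  if (length(presence_cells) < 10) {
    stop("need at least 10 presence cells", call. = FALSE)
  }
  if (is.null(background_cells)) {
    valid <- which(predictors$mask)
    background_cells <- if (length(valid) <= config$background_n) valid
    else sort(sample(valid, config$background_n))
  }
  X_bg <- stack_matrix(predictors, background_cells, vars)
  X_pr <- stack_matrix(predictors, presence_cells, vars)
  model <- fit_maxent_matrix(X_pr, X_bg, config)
  model$background_cells <- background_cells
  model$presence_cells <- presence_cells
  model$vars <- names(model$bounds$min)
  model
}

# Matrix-level fit: presence and background given as raw predictor matrices
# with identical named columns.
fit_maxent_matrix <- function(X_pr, X_bg, config = maxent_config()) {
  stopifnot(identical(colnames(X_pr), colnames(X_bg)))
  lo <- apply(X_bg, 2, min)
  hi <- apply(X_bg, 2, max)
  keep <- hi > lo
  if (!all(keep)) {
    warning("dropping degenerate predictor(s): ",
            paste(colnames(X_bg)[!keep], collapse = ", "), call. = FALSE)
    X_pr <- X_pr[, keep, drop = FALSE]
    X_bg <- X_bg[, keep, drop = FALSE]
    lo <- lo[keep]; hi <- hi[keep]
  }
  if (!ncol(X_bg)) stop("no usable predictors", call. = FALSE)
  classes <- if (identical(config$classes, "auto")) {
    auto_classes(nrow(X_pr))
  } else config$classes
  norm <- function(X) {
    Xn <- sweep(sweep(X, 2, lo), 2, hi - lo, "/")
    Xn[Xn < 0] <- 0; Xn[Xn > 1] <- 1
    Xn
  }
  feat_bg <- maxent_features(norm(X_bg), classes, config$n_knots)
  feat_pr <- maxent_features(norm(X_pr), classes, config$n_knots)
  m <- nrow(X_pr)
  s <- apply(feat_pr$F, 2, stats::sd)
  s <- pmax(s, 0.01)
  beta <- ifelse(feat_bg$meta$class == "hinge", 0.5, beta_lq(m))
  lambda <- config$reg_multiplier * beta * s / sqrt(m)
  fit <- fit_maxent_weights(feat_pr$F, feat_bg$F, lambda,
                            tol = config$tol, max_iter = config$max_iter)
  if (!all(is.finite(fit$weights))) {
    stop("maxent fit produced non-finite weights", call. = FALSE)
  }
  if (!fit$converged) {
    warning(sprintf(
      "maxent fit not converged after %d iterations (objective %.6g); consider raising max_iter",
      fit$n_iter, fit$objective), call. = FALSE)
  }
  structure(
    list(
      weights = fit$weights, meta = feat_bg$meta, classes = classes,
      n_knots = config$n_knots,
      bounds = list(min = lo, max = hi),
      lambda = lambda, logZ = fit$logZ, entropy = fit$entropy,
      converged = fit$converged, n_iter = fit$n_iter,
      objective = fit$objective, n_presence = m, config = config
    ),
    class = "maxent_model"
  )
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %d features (%s) over %d predictors; %d presences; %s after %d iterations\n",
    length(x$weights), paste(x$classes, collapse = "+"),
    length(x$bounds$min), x$n_presence,
    if (x$converged) "converged" else "NOT converged", x$n_iter
  ))
  invisible(x)
}

#' Predict suitability from a fitted Maxent model
#'
#' @param object a `maxent_model`.
#' @param newdata a [predictor_stack()] or a raw predictor matrix with the
#'   model's variables as named columns.
#' @param type `"logistic"` (default; probability-of-occurrence scale in
#'   `(0, 1)`) or `"raw"` (Gibbs density normalized over the training
#'   background).
#' @param cells optional cell subset when `newdata` is a stack (defaults to
#'   all valid cells).
#' @param ... unused.
#' @return If `newdata` is a stack, a matrix on its grid (`NA` off-mask);
#'   if a matrix, a numeric vector.
#' @export
predict.maxent_model <- function(object, newdata, type = c("logistic", "raw"),
                                 cells = NULL, ...) {
  type <- match.arg(type)
  as_grid <- inherits(newdata, "predictor_stack")
  if (as_grid) {
    if (is.null(cells)) cells <- which(newdata$mask)
    X <- stack_matrix(newdata, cells, names(object$bounds$min))
  } else {
    X <- newdata[, names(object$bounds$min), drop = FALSE]
  }
  lo <- object$bounds$min
  hi <- object$bounds$max
  Xn <- sweep(sweep(X, 2, lo), 2, hi - lo, "/")
  Xn[Xn < 0] <- 0; Xn[Xn > 1] <- 1
  F <- maxent_features(Xn, object$classes, object$n_knots)$F
  eta <- drop(F %*% object$weights)
  r <- exp(eta - object$logZ)
  out <- if (type == "raw") r else {
    cr <- exp(object$entropy) * r
    cr / (1 + cr)
  }
  if (as_grid) {
    g <- empty_layer(newdata$spec)
    g[cells] <- out
    g
  } else {
    out
  }
}

#' Ten-percent training-presence threshold
#'
#' The binary-conversion rule that keeps, as "suitable", the environmental
#' conditions of 90% of the training presences: the threshold is the
#' largest predicted value `t` among the training presences such that at
#' least 90% of them satisfy `p >= t`. With `n` distinct values this is the
#' `(n - ceiling(0.9 n) + 1)`-th smallest.
#'
#' @param p_train numeric vector of predicted suitability at the training
#'   presences.
#' @param percentile percent of training presences allowed below the
#'   threshold (default 10, the standard rule).
#' @return The threshold value.
#' @export
threshold_10pct <- function(p_train, percentile = 10) {
  stopifnot(length(p_train) >= 1, all(is.finite(p_train)),
            percentile >= 0, percentile < 100)
  n <- length(p_train)
  k <- n - ceiling((1 - percentile / 100) * n) + 1
  sort(p_train)[k]
}

#' Serialize a fitted Maxent model to JSON
#'
#' Writes everything needed to reproduce predictions — feature definitions,
#' fitted weights, normalization bounds, the normalizing constant and
#' entropy — to a plain JSON file; [maxent_from_json()] restores a model
#' whose predictions are identical to the original's.
#'
#' @param model a `maxent_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
maxent_to_json <- function(model, path) {
  stopifnot(inherits(model, "maxent_model"))
  obj <- list(
    classes = model$classes, n_knots = model$n_knots,
    variables = names(model$bounds$min),
    bounds_min = unname(model$bounds$min),
    bounds_max = unname(model$bounds$max),
    weights = model$weights, lambda = model$lambda,
    meta = model$meta,
    logZ = model$logZ, entropy = model$entropy,
    n_presence = model$n_presence,
    threshold = model$threshold %||% NULL
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname maxent_to_json
#' @export
maxent_from_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  lo <- stats::setNames(o$bounds_min, o$variables)
  hi <- stats::setNames(o$bounds_max, o$variables)
  structure(
    list(weights = o$weights, meta = as.data.frame(o$meta),
         classes = o$classes, n_knots = o$n_knots,
         bounds = list(min = lo, max = hi), lambda = o$lambda,
         logZ = o$logZ, entropy = o$entropy, converged = TRUE,
         n_iter = NA_integer_, objective = NA_real_,
         n_presence = o$n_presence, threshold = o$threshold,
         config = NULL),
    class = "maxent_model"
  )
}

#' Resampled Maxent fits (cross-validation or repeated splits)
#'
#' Fits one Maxent model per resampling run: 10-fold cross-validation
#' (`"cv10"`; folds disjoint and jointly exhaustive) or ten random 75/25
#' train/test splits (`"split75x10"`). All runs share one background sample
#' and one grid-wide feature expansion, so only the presence subset and the
#' regularization differ between runs. Each run records its train/test
#' cells, full-grid suitability map, ten-percent training threshold and
#' test AUC (test presences versus background).
#'
#' @param predictors a [predictor_stack()].
#' @param occ an [occurrence_set()] (or integer vector of presence cells).
#' @param scheme `"cv10"` or `"split75x10"`.
#' @param vars predictor layer names to use (default: all).
#' @param config a [maxent_config()].
#' @param seed integer seed controlling the partitions and the background
#'   sample.
#' @return A `run_set`: list with `runs` (each: `model`, `train`, `test`,
#'   `p` grid matrix, `threshold`, `test_auc`), `scheme`, `background`,
#'   `vars`, `spec`.
#' @export
resample_fit <- function(predictors, occ, scheme = c("cv10", "split75x10"),
                         vars = NULL, config = maxent_config(), seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(predictors, "predictor_stack"))
  cells <- if (inherits(occ, "occurrence_set")) occ$cells else as.integer(occ)
  n <- length(cells)
  n_runs <- 10L
  if (scheme == "cv10" && n < n_runs) {
    stop("fewer presences than folds", call. = FALSE)
  }
  set.seed(seed)
  valid <- which(predictors$mask)
  background <- if (length(valid) <= config$background_n) valid
  else sort(sample(valid, config$background_n))

  if (is.null(vars)) vars <- names(predictors$layers)
  X_bg <- stack_matrix(predictors, background, vars)
  lo <- apply(X_bg, 2, min)
  hi <- apply(X_bg, 2, max)
  keep <- hi > lo
  if (!all(keep)) {
    warning("dropping degenerate predictor(s): ",
            paste(vars[!keep], collapse = ", "), call. = FALSE)
    vars <- vars[keep]
    lo <- lo[keep]; hi <- hi[keep]
  }
  classes <- if (identical(config$classes, "auto")) {
    auto_classes(if (scheme == "cv10") n - floor(n / n_runs) else
      floor(0.75 * n))
  } else config$classes
  # one normalized feature expansion for every valid cell, reused by all runs
  X_all <- stack_matrix(predictors, valid, vars)
  Xn <- sweep(sweep(X_all, 2, lo), 2, hi - lo, "/")
  Xn[Xn < 0] <- 0; Xn[Xn > 1] <- 1
  feat <- maxent_features(Xn, classes, config$n_knots)
  row_of <- integer(n_cells(predictors$spec))
  row_of[valid] <- seq_along(valid)
  bg_rows <- row_of[background]
  F_bg <- feat$F[bg_rows, , drop = FALSE]

  # partitions
  perm <- sample(n)
  parts <- vector("list", n_runs)
  if (scheme == "cv10") {
    fold <- rep_len(seq_len(n_runs), n)[order(perm)]   # balanced fold sizes
    for (r in seq_len(n_runs)) parts[[r]] <- list(test = which(fold == r))
  } else {
    n_train <- floor(0.75 * n)
    for (r in seq_len(n_runs)) {
      tr <- sample(n, n_train)
      parts[[r]] <- list(test = setdiff(seq_len(n), tr))
    }
  }

  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    test_i <- parts[[r]]$test
    train_cells <- cells[-test_i]
    test_cells <- cells[test_i]
    F_tr <- feat$F[row_of[train_cells], , drop = FALSE]
    m <- length(train_cells)
    s <- pmax(apply(F_tr, 2, stats::sd), 0.01)
    beta <- ifelse(feat$meta$class == "hinge", 0.5, beta_lq(m))
    lambda <- config$reg_multiplier * beta * s / sqrt(m)
    fit <- fit_maxent_weights(F_tr, F_bg, lambda,
                              tol = config$tol, max_iter = config$max_iter)
    if (!fit$converged) {
      warning(sprintf("run %d: maxent fit not converged after %d iterations",
                      r, fit$n_iter), call. = FALSE)
    }
    eta_all <- drop(feat$F %*% fit$weights)
    cr <- exp(fit$entropy) * exp(eta_all - fit$logZ)
    p_all <- cr / (1 + cr)
    p_grid <- empty_layer(predictors$spec)
    p_grid[valid] <- p_all
    thr <- threshold_10pct(p_grid[train_cells])
    model <- structure(
      list(weights = fit$weights, meta = feat$meta, classes = classes,
           n_knots = config$n_knots,
           bounds = list(min = lo, max = hi),
           lambda = lambda, logZ = fit$logZ, entropy = fit$entropy,
           converged = fit$converged, n_iter = fit$n_iter,
           objective = fit$objective, n_presence = m, config = config),
      class = "maxent_model"
    )
    runs[[r]] <- list(
      model = model, train = train_cells, test = test_cells,
      p = p_grid, threshold = thr,
      test_auc = auc(p_grid[test_cells], p_grid[background])
    )
  }
  structure(
    list(runs = runs, scheme = scheme, background = background, vars = vars,
         spec = predictors$spec,
         species = if (inherits(occ, "occurrence_set")) occ$species else NA),
    class = "run_set"
  )
}

#' @export
print.run_set <- function(x, ...) {
  cat(sprintf(
    "<run_set> %s, %d runs over %s; mean test AUC %.3f\n",
    x$scheme, length(x$runs), paste(x$vars, collapse = ", "),
    mean(vapply(x$runs, `[[`, numeric(1), "test_auc"))
  ))
  invisible(x)
}

#' Agreement-masked ensemble of resampled runs
#'
#' Combines the thresholded binary maps of a [resample_fit()] run set into
#' an ensemble: a cell is called "present" only where at least
#' `min_agreement` of the runs predict presence (p at or above their own
#' training threshold); inside the presence area the ensemble carries the
#' mean suitability over all runs, outside it the effective suitability is
#' zero. The strict all-10 rule suits wild taxa; a more relaxed 7-of-10
#' rule suits a managed crop.
#'
#' @param run_set a `run_set` from [resample_fit()].
#' @param min_agreement minimum number of agreeing runs (1..n_runs).
#' @return An `ensemble_map`: `mean_p` (mean suitability grid), `presence`
#'   (logical grid), `effective_p` (mean_p inside presence, 0 outside),
#'   `agreement` (count grid), `min_agreement`, `n_runs`, `spec`.
#' @export
ensemble <- function(run_set, min_agreement) {
  stopifnot(inherits(run_set, "run_set"))
  n_runs <- length(run_set$runs)
  stopifnot(min_agreement >= 1, min_agreement <= n_runs)
  spec <- run_set$spec
  agree <- matrix(0L, spec$nrow, spec$ncol)
  mean_p <- matrix(0, spec$nrow, spec$ncol)
  for (run in run_set$runs) {
    stopifnot(nrow(run$p) == spec$nrow)
    agree <- agree + (!is.na(run$p) & run$p >= run$threshold)
    mean_p <- mean_p + run$p
  }
  mean_p <- mean_p / n_runs
  presence <- agree >= min_agreement
  presence[is.na(mean_p)] <- FALSE
  effective_p <- ifelse(presence, mean_p, 0)
  effective_p[is.na(mean_p)] <- NA_real_
  structure(
    list(mean_p = mean_p, presence = presence, effective_p = effective_p,
         agreement = agree, min_agreement = as.integer(min_agreement),
         n_runs = n_runs, spec = spec, species = run_set$species),
    class = "ensemble_map"
  )
}

#' @export
print.ensemble_map <- function(x, ...) {
  cat(sprintf(
    "<ensemble_map> %s: presence in %d cells (>= %d of %d runs agree)\n",
    if (is.na(x$species)) "unnamed" else x$species,
    sum(x$presence, na.rm = TRUE), x$min_agreement, x$n_runs
  ))
  invisible(x)
}
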