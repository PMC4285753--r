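#' Rank-based AUC for presence versus background scores
#'
#' Area under the ROC curve computed from ranks (the Mann-Whitney
#' statistic), with ties counted one half:
#' `AUC = P(score_presence > score_background) + 0.5 P(equal)`.
#'
#' @param presence_scores,background_scores numeric score vectors (both
#'   non-empty).
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.9, 0.8), c(0.1, 0.2))  # 1: perfect separation
#' @export
auc <- function(presence_scores, background_scores) {
  n1 <- length(presence_scores)
  n2 <- length(background_scores)
  if (n1 == 0 || n2 == 0) stop("empty score set", call. = FALSE)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Null-model AUC significance test
#'
#' Fits the same resampled Maxent configuration to pseudo-species whose
#' "presences" are cells drawn uniformly at random from the valid mask, and
#' summarizes the distribution of their mean test AUC. A real species'
#' model is considered significantly better than chance when its observed
#' mean test AUC exceeds the null distribution; with presence-only data the
#' expected null AUC sits just below 0.5 because flexible features overfit
#' the random training folds.
#'
#' @param n_presences presences per null replicate (use the real species'
#'   record count).
#' @param predictors a [predictor_stack()].
#' @param n_null number of null replicates.
#' @param scheme,vars,config forwarded to [resample_fit()].
#' @param observed_auc optional observed mean test AUC to compare against.
#' @param seed integer seed.
#' @return A `null_model_report`: per-replicate mean test AUCs, their
#'   mean/range, the observed AUC (if given) and a pass flag
#'   (`observed > max(null)` convention is left to the caller; the report
#'   stores `observed > mean(null)` as `pass`).
#' @export
null_model_test <- function(n_presences, predictors, n_null = 20,
                            scheme = "cv10", vars = NULL,
                            config = maxent_config(),
                            observed_auc = NULL, seed = 1) {
  stopifnot(n_presences >= 10, n_null >= 1)
  valid <- which(predictors$mask)
  null_auc <- numeric(n_null)
  n_failed <- 0L
  for (i in seq_len(n_null)) {
    set.seed(seed + 1000L * i)
    cells <- sample(valid, n_presences)
    rs <- tryCatch(
      resample_fit(predictors, cells, scheme = scheme, vars = vars,
                   config = config, seed = seed + 1000L * i + 1L),
      error = function(e) NULL
    )
    if (is.null(rs)) {
      n_failed <- n_failed + 1L
      null_auc[i] <- NA_real_
    } else {
      null_auc[i] <- mean(vapply(rs$runs, `[[`, numeric(1), "test_auc"))
    }
  }
  ok <- !is.na(null_auc)
  structure(
    list(
      null_auc = null_auc, mean_null = mean(null_auc[ok]),
      range_null = range(null_auc[ok]), n_failed = n_failed,
      observed_auc = observed_auc,
      pass = if (!is.null(observed_auc)) observed_auc > mean(null_auc[ok])
      else NA
    ),
    class = "null_model_report"
  )
}

#' @export
print.null_model_report <- function(x, ...) {
  cat(sprintf(
    "<null_model_report> %d replicates: mean null AUC %.3f (range %.3f-%.3f)\n",
    length(x$null_auc), x$mean_null, x$range_null[1], x$range_null[2]
  ))
  if (!is.null(x$observed_auc)) {
    cat(sprintf("  observed AUC %.3f -> %s\n", x$observed_auc,
                if (isTRUE(x$pass)) "better than null mean" else "NOT better"))
  }
  invisible(x)
}

#' Permutation importance of each predictor (AUC drop)
#'
#' For every run of a fitted [resample_fit()] run set and every predictor,
#' replaces the predictor's values at the evaluation points (test presences
#' and background cells) with values drawn at random from the background
#' distribution of that predictor, re-scores the model, and records the
#' drop in test AUC. Larger drops mean the model leans more heavily on that
#' variable. Per-variable means and percentile confidence intervals are
#' obtained by bootstrapping the per-run drops.
#'
#' @param run_set a `run_set` from [resample_fit()].
#' @param predictors the [predictor_stack()] the runs were fitted on.
#' @param n_boot bootstrap replicates for the CI (default 10000).
#' @param ci percentile interval coverage (default 0.95).
#' @param seed integer seed for the permutation draws and bootstrap.
#' @return An `importance_report`: `summary` data.frame (variable,
#'   mean_drop, ci_low, ci_high, n_runs) sorted by decreasing mean drop,
#'   and `drops` (runs x variables matrix of raw AUC drops).
#' @export
permutation_importance <- function(run_set, predictors, n_boot = 10000,
                                   ci = 0.95, seed = 1) {
  stopifnot(inherits(run_set, "run_set"))
  vars <- run_set$vars
  bg <- run_set$background
  X_bg <- stack_matrix(predictors, bg, vars)
  n_runs <- length(run_set$runs)
  drops <- matrix(NA_real_, n_runs, length(vars),
                  dimnames = list(NULL, vars))
  set.seed(seed)
  for (r in seq_len(n_runs)) {
    run <- run_set$runs[[r]]
    model <- run$model
    eval_cells <- c(run$test, bg)
    n_test <- length(run$test)
    X_eval <- stack_matrix(predictors, eval_cells, vars)
    mvars <- names(model$bounds$min)
    norm <- function(X) {
      Xn <- sweep(sweep(X[, mvars, drop = FALSE], 2, model$bounds$min), 2,
                  model$bounds$max - model$bounds$min, "/")
      Xn[Xn < 0] <- 0; Xn[Xn > 1] <- 1
      Xn
    }
    feat <- maxent_features(norm(X_eval), model$classes, model$n_knots)
    eta_base <- drop(feat$F %*% model$weights)
    base_auc <- run$test_auc
    for (v in vars) {
      if (!v %in% mvars) {            # dropped as degenerate during the fit
        drops[r, v] <- 0
        next
      }
      # features are variable-separable, so only the permuted variable's
      # contribution to the linear predictor needs recomputing
      cols_v <- which(feat$meta$var == v)
      Xp <- X_eval
      Xp[, v] <- sample(X_bg[, v], nrow(Xp), replace = TRUE)
      fp <- maxent_features(norm(Xp)[, v, drop = FALSE], model$classes,
                            model$n_knots)
      eta <- eta_base - drop(feat$F[, cols_v, drop = FALSE] %*%
                               model$weights[cols_v]) +
        drop(fp$F %*% model$weights[cols_v])
      cr <- exp(model$entropy) * exp(eta - model$logZ)
      p <- cr / (1 + cr)
      drops[r, v] <- base_auc - auc(p[seq_len(n_test)], p[-seq_len(n_test)])
    }
  }
  alpha <- (1 - ci) / 2
  summary <- do.call(rbind, lapply(vars, function(v) {
    d <- drops[, v]
    if (n_runs > 1) {
      boot_means <- vapply(seq_len(n_boot), function(b) {
        mean(d[sample.int(n_runs, n_runs, replace = TRUE)])
      }, numeric(1))
      qs <- stats::quantile(boot_means, c(alpha, 1 - alpha), names = FALSE)
    } else {
      qs <- c(d, d)  # single run: CI degenerates to a point
    }
    data.frame(variable = v, mean_drop = mean(d),
               ci_low = qs[1], ci_high = qs[2], n_runs = n_runs,
               stringsAsFactors = FALSE)
  }))
  summary <- summary[order(-summary$mean_drop), ]
  rownames(summary) <- NULL
  structure(
    list(summary = summary, drops = drops, n_boot = n_boot, ci = ci,
         degenerate_ci = n_runs == 1),
    class = "importance_report"
  )
}

#' @export
print.importance_report <- function(x, ...) {
  cat("<importance_report> AUC drop after background permutation\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Correlation between crop extent and predicted suitability
#'
#' Spearman's rho between per-cell crop extent and predicted probability of
#' occurrence over the occupied cells, with significance from a resampling
#' null: pairings are re-drawn at random (with replacement) from the two
#' marginal distributions, and the two-sided exceedance proportion of
#' `|rho_null| >= |rho_observed|` is reported.
#'
#' @param extent matrix of crop hectares per cell.
#' @param p matrix of predicted suitability on the same grid.
#' @param n_resamples null resamples (default 9999).
#' @param seed integer seed.
#' @return List with `rho`, `p_value` (two-sided,
#'   `(1 + exceedances) / (1 + n_resamples)`), `n_cells`, `n_resamples`.
#' @export
extent_probability_correlation <- function(extent, p, n_resamples = 9999,
                                           seed = 1) {
  stopifnot(identical(dim(extent), dim(p)))
  sel <- which(!is.na(extent) & extent > 0 & !is.na(p))
  if (length(sel) < 3) stop("need at least 3 crop cells", call. = FALSE)
  e <- extent[sel]
  q <- p[sel]
  rho <- stats::cor(e, q, method = "spearman")
  set.seed(seed)
  n <- length(sel)
  exceed <- 0L
  for (i in seq_len(n_resamples)) {
    r0 <- stats::cor(e[sample.int(n, n, replace = TRUE)],
                     q[sample.int(n, n, replace = TRUE)],
                     method = "spearman")
    if (abs(r0) >= abs(rho)) exceed <- exceed + 1L
  }
  list(rho = rho, p_value = (1 + exceed) / (1 + n_resamples),
       n_cells = n, n_resamples = n_resamples)
}
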