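test_that("feature expansions hit their boundary values", {
  x <- matrix(c(0, 0.25, 0.5, 1), ncol = 1, dimnames = list(NULL, "v"))
  lin <- maxent_features(x, "linear")
  expect_equal(as.vector(lin$F), c(0, 0.25, 0.5, 1))
  quad <- maxent_features(x, "quadratic")
  expect_equal(as.vector(quad$F), c(0, 0.0625, 0.25, 1))
  hin <- maxent_features(x, "hinge", n_knots = 2)
  # forward hinge with knot 0.5: 0 at x = 0.5, 1 at x = 1
  fcol <- which(hin$meta$dir == "fwd" & hin$meta$knot == 0.5)
  expect_equal(unname(hin$F[3, fcol]), 0)
  expect_equal(unname(hin$F[4, fcol]), 1)
})

test_that("features stay in [0,1] and hinges are piecewise linear", {
  set.seed(14)
  x <- matrix(runif(400), ncol = 2, dimnames = list(NULL, c("a", "b")))
  f <- maxent_features(x, c("linear", "quadratic", "hinge"), n_knots = 10)
  expect_true(all(f$F >= 0 & f$F <= 1))
  # dense-grid check of the hinge formulas
  g <- matrix(seq(0, 1, length.out = 501), ncol = 1,
              dimnames = list(NULL, "a"))
  fh <- maxent_features(g, "hinge", n_knots = 10)
  for (j in seq_len(ncol(fh$F))) {
    k <- fh$meta$knot[j]
    want <- if (fh$meta$dir[j] == "fwd") pmax(0, (g[, 1] - k) / (1 - k))
    else pmax(0, (k - g[, 1]) / k)
    expect_equal(fh$F[, j], want, tolerance = 1e-12)
  }
})

test_that("fitted suitability tracks an obvious binary signal", {
  set.seed(30)
  gs <- grid_spec(20, 20)
  strat <- matrix(rep(c(0, 1), each = 200), 20, 20)   # A half, B half
  noise <- matrix(runif(400), 20, 20)
  preds <- predictor_stack(list(strat = strat, noise = noise), gs)
  pres <- sample(which(strat == 1), 60)
  m <- fit_maxent(preds, pres, config = maxent_config(classes = "linear"))
  p <- predict(m, preds)
  expect_gt(mean(p[strat == 1]), mean(p[strat == 0]))
  expect_true(all(p > 0 & p < 1, na.rm = TRUE))
})

test_that("the raw distribution is a probability over the background", {
  set.seed(31)
  preds <- random_stack(seed = 31)
  pres <- sample(which(preds$mask), 50)
  m <- fit_maxent(preds, pres,
                  config = maxent_config(classes = c("linear", "quadratic")))
  raw_bg <- predict(m, preds, type = "raw", cells = m$background_cells)
  expect_equal(sum(raw_bg[m$background_cells]), 1, tolerance = 1e-9)
})

test_that("linear-feature fits agree with a BFGS oracle on the same likelihood", {
  set.seed(33)
  n_bg <- 400
  X_bg <- cbind(a = runif(n_bg), b = runif(n_bg))
  # presence biased towards high a: overlapping, no separation
  keep <- runif(n_bg) < plogis(3 * (X_bg[, "a"] - 0.5))
  X_pr <- X_bg[keep, , drop = FALSE][1:60, ]
  cfg <- maxent_config(classes = "linear", reg_multiplier = 0,
                       tol = 1e-12, max_iter = 5000)
  m <- pollavail:::fit_maxent_matrix(X_pr, X_bg, cfg)
  # oracle: generic smooth convex optimizer on the identical objective
  lo <- apply(X_bg, 2, min); hi <- apply(X_bg, 2, max)
  nrm <- function(X) sweep(sweep(X, 2, lo), 2, hi - lo, "/")
  F_bg <- nrm(X_bg); F_pr <- nrm(X_pr)
  obj <- function(w) {
    eta <- F_bg %*% w
    mx <- max(eta)
    (mx + log(sum(exp(eta - mx)))) - mean(F_pr %*% w)
  }
  o <- optim(c(0, 0), obj, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 1000))
  expect_lt(max(abs(m$weights - o$par)), 1e-4)
})

test_that("a species with a known response is recovered (5 seeds)", {
  for (seed in 1:5) {
    sc <- tiny_scenario(seed = 100 + seed, nrow = 25, ncol = 25, species = list(
      species_response("sp", var = "Bio06", family = "logistic",
                       center = 0, width = 0.8, pmax = 0.9, n_records = 300)
    ))
    scn <- generate_scenario(sc)
    occ <- scn$species$occurrences$sp
    m <- fit_maxent(scn$predictors, occ$cells, vars = c("Bio06", "Bio15"))
    p <- predict(m, scn$predictors)
    truth <- scn$species$truth$sp
    sel <- which(!is.na(truth))
    expect_gt(cor(p[sel], truth[sel], method = "spearman"), 0.9)
  }
})

test_that("resampling partitions obey their schemes and seeds", {
  preds <- random_stack(seed = 40)
  set.seed(1)
  occ30 <- sample(which(preds$mask), 30)
  cfg <- maxent_config(classes = "linear", max_iter = 50)
  rs <- resample_fit(preds, occ30, "cv10", config = cfg, seed = 5)
  tests <- lapply(rs$runs, `[[`, "test")
  expect_true(all(lengths(tests) == 3))
  expect_equal(sort(unlist(tests)), sort(occ30))         # exhaustive
  expect_equal(anyDuplicated(unlist(tests)), 0)          # disjoint
  for (run in rs$runs) {
    expect_length(intersect(run$train, run$test), 0)
  }
  occ100 <- sample(which(preds$mask), 100)
  rs2 <- resample_fit(preds, occ100, "split75x10", config = cfg, seed = 6)
  expect_true(all(vapply(rs2$runs, function(r) length(r$train), numeric(1)) == 75))
  expect_true(all(vapply(rs2$runs, function(r) length(r$test), numeric(1)) == 25))
  # determinism
  rs3 <- resample_fit(preds, occ100, "split75x10", config = cfg, seed = 6)
  expect_identical(lapply(rs2$runs, `[[`, "test"),
                   lapply(rs3$runs, `[[`, "test"))
  expect_identical(rs2$runs[[1]]$model$weights, rs3$runs[[1]]$model$weights)
  expect_error(resample_fit(preds, occ30[1:5], "cv10", config = cfg),
               "fewer presences")
})

test_that("the training-presence threshold retains 90% of presences", {
  set.seed(50)
  p100 <- runif(100)
  thr <- threshold_10pct(p100)
  expect_equal(sum(p100 >= thr), 90)
  # ties: all equal values are retained
  expect_equal(threshold_10pct(rep(0.4, 25)), 0.4)
  expect_equal(sum(rep(0.4, 25) >= threshold_10pct(rep(0.4, 25))), 25)
  # random vectors match the sort-and-index oracle
  for (seed in 1:10) {
    set.seed(seed)
    p <- runif(sample(10:200, 1))
    expect_equal(threshold_10pct(p), oracle_threshold(p))
  }
})

test_that("ensemble agreement rules behave as specified", {
  gs <- grid_spec(3, 3)
  mk_run <- function(p, thr) list(p = p, threshold = thr)
  base <- matrix(0.1, 3, 3)
  runs <- lapply(1:10, function(i) {
    p <- base
    p[1, 1] <- if (i <= 9) 0.9 else 0.2   # cell 1: present in 9/10 runs
    p[2, 2] <- if (i <= 7) 0.9 else 0.2   # cell 5: present in 7/10
    p[3, 3] <- if (i == 1) 0.9 else 0.2   # cell 9: present in 1/10
    mk_run(p, 0.5)
  })
  rs <- structure(list(runs = runs, scheme = "cv10", background = 1:9,
                       vars = "v", spec = gs, species = "x"),
                  class = "run_set")
  expect_false(ensemble(rs, 10)$presence[1, 1])   # 9/10 misses all-10 rule
  expect_true(ensemble(rs, 9)$presence[1, 1])
  expect_true(ensemble(rs, 7)$presence[2, 2])     # 7/10 meets the 7 rule
  expect_false(ensemble(rs, 8)$presence[2, 2])
  u <- ensemble(rs, 1)
  expect_true(all(u$presence[cbind(c(1, 2, 3), c(1, 2, 3))]))  # union
  # monotonicity: larger agreement never enlarges the presence area
  areas <- vapply(1:10, function(k) sum(ensemble(rs, k)$presence),
                  numeric(1))
  expect_true(all(diff(areas) <= 0))
  # effective p is zero outside presence
  e7 <- ensemble(rs, 7)
  expect_equal(e7$effective_p[3, 3], 0)
  expect_equal(e7$effective_p[2, 2], e7$mean_p[2, 2])
})

test_that("JSON serialization round-trips model predictions exactly", {
  preds <- random_stack(seed = 45)
  set.seed(2)
  pres <- sample(which(preds$mask), 60)
  m <- fit_maxent(preds, pres)
  path <- withr::local_tempfile(fileext = ".json")
  maxent_to_json(m, path)
  m2 <- maxent_from_json(path)
  expect_equal(predict(m2, preds), predict(m, preds), tolerance = 1e-12)
})

test_that("test AUC rises monotonically with the true signal strength", {
  # same world, same records budget; only the steepness of the species'
  # response to its driver changes
  widths <- c(8, 2.5, 0.8)   # weak -> strong response to Bio06
  mean_auc <- sapply(widths, function(w) {
    aucs <- sapply(1:2, function(seed) {
      sc <- tiny_scenario(seed = 200 + seed, nrow = 25, ncol = 25,
        species = list(species_response("sp", var = "Bio06",
                                        family = "logistic", center = 0,
                                        width = w, pmax = 0.9,
                                        n_records = 250)))
      scn <- generate_scenario(sc)
      rs <- resample_fit(scn$predictors, scn$species$occurrences$sp,
                         "cv10", vars = c("Bio06", "Bio15"),
                         seed = 300 + seed)
      mean(vapply(rs$runs, `[[`, numeric(1), "test_auc"))
    })
    mean(aucs)
  })
  expect_true(all(diff(mean_auc) > 0))
})
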