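# Shared in-code fixtures: tiny scenarios and hand-built model containers.

tiny_grid <- function(nrow = 20, ncol = 20) grid_spec(nrow, ncol, cellsize = 5000)

tiny_scenario <- function(seed = 1, nrow = 20, ncol = 20, ...) {
  scenario_spec(grid = tiny_grid(nrow, ncol), seed = seed, ...)
}

random_climate <- function(seed = 1, nrow = 4, ncol = 5) {
  set.seed(seed)
  gs <- grid_spec(nrow, ncol)
  tmin <- array(rnorm(nrow * ncol * 12, 2, 5), c(nrow, ncol, 12))
  tmax <- tmin + array(runif(nrow * ncol * 12, 0.5, 12), c(nrow, ncol, 12))
  prec <- array(rgamma(nrow * ncol * 12, 2, 1 / 40), c(nrow, ncol, 12))
  monthly_climate(tmin, tmax, prec, gs)
}

# A predictor stack of smooth independent fields, for model-level tests that
# do not need the climate machinery.
random_stack <- function(seed = 1, nrow = 20, ncol = 20, vars = c("a", "b")) {
  set.seed(seed)
  gs <- grid_spec(nrow, ncol)
  layers <- lapply(seq_along(vars), function(i) {
    outer(seq_len(nrow), seq_len(ncol), function(r, c) {
      sin(i * r / nrow * pi) + cos(i * c / ncol * pi)
    }) + matrix(rnorm(nrow * ncol, sd = 0.3), nrow, ncol)
  })
  names(layers) <- vars
  predictor_stack(layers, gs)
}

# Hand-built ensemble_map, for service-layer tests decoupled from fitting.
fake_ensemble <- function(p, presence = NULL, species = "fake",
                          min_agreement = 10L, n_runs = 10L) {
  spec <- grid_spec(nrow(p), ncol(p))
  if (is.null(presence)) presence <- !is.na(p) & p > 0
  effective_p <- ifelse(presence, p, 0)
  effective_p[is.na(p)] <- NA_real_
  structure(
    list(mean_p = p, presence = presence, effective_p = effective_p,
         agreement = presence * n_runs, min_agreement = min_agreement,
         n_runs = n_runs, spec = spec, species = species),
    class = "ensemble_map"
  )
}

pdm_vars_default <- c("Bio03", "Bio07", "Bio09", "Bio11", "Bio15", "Bio19")
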