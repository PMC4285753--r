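#' Change patterns for future-scenario construction
#'
#' The synthetic future climate is derived from the present one by applying,
#' per climate component, one of three qualitative change classes observed
#' when comparing baseline and mid-century projections: no change, a
#' systematic shift of the whole distribution, or a change in the spread or
#' shape of the distribution.
#'
#' @param delta additive shift (degrees C for temperature, mm/month for
#'   precipitation).
#' @param scale multiplicative factor applied to the seasonal (monthly)
#'   deviations around each cell's annual mean; `scale = 2` doubles the
#'   temperature seasonality (Bio04) or the precipitation seasonality.
#' @return A change-pattern object (class `change_pattern`).
#' @export
change_none <- function() {
  structure(list(kind = "none"), class = "change_pattern")
}

#' @rdname change_none
#' @export
change_shift <- function(delta) {
  stopifnot(is.finite(delta))
  structure(list(kind = "shift", delta = delta), class = "change_pattern")
}

#' @rdname change_none
#' @export
change_reshape <- function(scale = 2) {
  stopifnot(is.finite(scale), scale > 0)
  structure(list(kind = "reshape", scale = scale), class = "change_pattern")
}

#' Species response definition for the synthetic generator
#'
#' Defines a species' true occurrence probability as a known function of one
#' predictor layer, so model-recovery can be tested against ground truth.
#'
#' @param name species label.
#' @param var predictor layer name the species responds to (e.g. `"Bio06"`);
#'   ignored for `family = "uniform"`.
#' @param family `"gaussian"` (bump with optimum `center` and width `width`),
#'   `"logistic"` (sigmoid increasing in `var` with midpoint `center` and
#'   scale `width`), or `"uniform"` (no environmental signal).
#' @param center,width response location and spread, in the units of `var`.
#' @param pmax maximum occurrence probability (in `[0, 1]`).
#' @param n_records number of raw sighting records to draw.
#' @return A `species_response` object.
#' @export
species_response <- function(name, var = NULL,
                             family = c("gaussian", "logistic", "uniform"),
                             center = 0, width = 1, pmax = 0.9,
                             n_records = 471) {
  family <- match.arg(family)
  stopifnot(pmax >= 0, pmax <= 1, n_records >= 1)
  if (family != "uniform" && (is.null(var) || width <= 0)) {
    stop("non-uniform responses need a driver variable and width > 0",
         call. = FALSE)
  }
  structure(list(name = name, var = var, family = family, center = center,
                 width = width, pmax = pmax,
                 n_records = as.integer(n_records)),
            class = "species_response")
}

#' Scenario specification for the synthetic generator
#'
#' Collects everything that defines one synthetic study system: grid
#' geometry, the RNG seed, the per-component future change patterns, the
#' species list with their true responses, and the crop-extent settings.
#' Defaults emulate the British orchard-pollinator study system at desk
#' scale: a 50 x 50 grid of 5 km cells, a future with uniformly warmer
#' temperatures (+2 degrees C), doubled temperature seasonality and
#' unchanged precipitation, and a crop occupying 14% of cells.
#'
#' @param grid a [grid_spec()] (default 50 x 50, 5 km cells).
#' @param seed integer RNG seed; the generator is fully deterministic
#'   given the seed.
#' @param change named list of [change_none()]/[change_shift()]/
#'   [change_reshape()] patterns for components `temp`, `temp_seasonality`,
#'   `prec`, `prec_seasonality`.
#' @param species list of [species_response()] definitions.
#' @param crop a [species_response()] describing crop climatic suitability
#'   (drives where synthetic orchards are placed).
#' @param crop_fraction proportion of valid cells containing crop.
#' @param crop_total_ha total crop extent to distribute, in hectares.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(grid = grid_spec(50, 50, cellsize = 5000),
                          seed = 1,
                          change = list(
                            temp = change_shift(2),
                            temp_seasonality = change_reshape(2),
                            prec = change_none(),
                            prec_seasonality = change_none()
                          ),
                          species = default_species_set(),
                          crop = species_response(
                            "orchard", var = "Bio04", family = "gaussian",
                            center = 450, width = 120, pmax = 0.9,
                            n_records = 1354
                          ),
                          crop_fraction = 0.14,
                          crop_total_ha = 12200) {
  stopifnot(inherits(grid, "grid_spec"))
  stopifnot(crop_fraction >= 0, crop_fraction <= 1, crop_total_ha >= 0)
  known <- c("temp", "temp_seasonality", "prec", "prec_seasonality")
  base <- list(temp = change_none(), temp_seasonality = change_none(),
               prec = change_none(), prec_seasonality = change_none())
  if (length(change)) {
    bad <- setdiff(names(change), known)
    if (length(bad)) {
      stop("unknown change components: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    base[names(change)] <- change
  }
  for (sp in species) stopifnot(inherits(sp, "species_response"))
  structure(
    list(grid = grid, seed = as.integer(seed), change = base,
         species = species, crop = crop, crop_fraction = crop_fraction,
         crop_total_ha = crop_total_ha),
    class = "scenario_spec"
  )
}

#' Default synthetic pollinator community
#'
#' Three species spanning the signal range used throughout the examples: a
#' cold-limited species driven by winter minimum temperature, a species tied
#' to precipitation seasonality, and one with no climate signal. Record
#' counts sit inside the 26-2096 per-species range typical of opportunistic
#' recording-scheme data, with the middle species at the bee median of 471.
#'
#' @return List of [species_response()] objects.
#' @export
default_species_set <- function() {
  list(
    species_response("sp_coldlim", var = "Bio06", family = "logistic",
                     center = 0, width = 0.8, pmax = 0.9, n_records = 471),
    species_response("sp_rainseas", var = "Bio15", family = "gaussian",
                     center = 30, width = 12, pmax = 0.8, n_records = 650),
    species_response("sp_uniform", family = "uniform", pmax = 0.5,
                     n_records = 150)
  )
}

# Smoothed Gaussian random field: white noise convolved with a separable
# Gaussian kernel (edge-renormalized), scaled to unit marginal SD.
smooth_field <- function(nrow, ncol, range_cells = 6) {
  k <- function(n) {
    half <- max(1L, ceiling(3 * range_cells))
    w <- stats::dnorm(seq(-half, half), sd = range_cells)
    m <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmax(1L, i - half):pmin(n, i + half)
      m[i, j] <- w[j - i + half + 1]
      m[i, ] <- m[i, ] / sum(m[i, ])
    }
    m
  }
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  s <- k(nrow) %*% z %*% t(k(ncol))
  s / stats::sd(as.vector(s))
}

#' Generate a present/future pair of monthly climate stacks
#'
#' Builds spatially autocorrelated monthly climate fields (a deterministic
#' latitudinal gradient plus smoothed Gaussian noise, with a sinusoidal
#' seasonal cycle peaking in July) and derives the future stack by applying
#' the scenario's change patterns to the same underlying fields. With all
#' patterns set to none the two stacks are identical; a `temp` shift adds a
#' constant to all monthly temperatures; a `temp_seasonality` reshape with
#' factor `s` multiplies each cell's monthly temperature deviations around
#' its annual mean by `s` (so Bio04 scales exactly by `s`); precipitation
#' patterns act analogously and are floored at zero.
#'
#' @param spec a [scenario_spec()].
#' @return List with elements `present` and `future`, both
#'   [monthly_climate()] objects on `spec$grid`.
#' @export
generate_climate <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  gs <- spec$grid
  set.seed(spec$seed)

  north <- matrix(rep(seq(1, 0, length.out = gs$nrow), gs$ncol),
                  gs$nrow, gs$ncol)                       # 1 = north edge
  west <- matrix(rep(seq(1, 0, length.out = gs$ncol), each = gs$nrow),
                 gs$nrow, gs$ncol)
  tbar <- 11 - 5 * north + 1.2 * smooth_field(gs$nrow, gs$ncol)
  amp <- pmax(5 + 1.5 * north + 0.8 * smooth_field(gs$nrow, gs$ncol), 2)
  dr <- pmax(6 + 1.5 * smooth_field(gs$nrow, gs$ncol), 2)
  pbar <- pmax(60 + 45 * west + 18 * smooth_field(gs$nrow, gs$ncol), 5)
  pamp <- 0.25 + 0.15 * smooth_field(gs$nrow, gs$ncol)

  month_t <- cos(2 * pi * ((1:12) - 7) / 12)   # +1 in July, -1 in January
  month_p <- cos(2 * pi * ((1:12) - 1) / 12)   # wetter winters

  build <- function(t_shift, seas_scale, p_shift, pseas_scale) {
    tmin <- tmax <- prec <- array(0, c(gs$nrow, gs$ncol, 12))
    for (m in 1:12) {
      tmean <- tbar + t_shift + seas_scale * amp * month_t[m]
      tmin[, , m] <- tmean - dr / 2
      tmax[, , m] <- tmean + dr / 2
      prec[, , m] <- pmax(pbar + p_shift +
                            pseas_scale * pamp * pbar * month_p[m], 0)
    }
    list(tmin = tmin, tmax = tmax, prec = prec)
  }
  par_of <- function(chg, shift_default = 0, scale_default = 1) {
    switch(chg$kind,
      none = c(shift_default, scale_default),
      shift = c(chg$delta, scale_default),
      reshape = c(shift_default, chg$scale)
    )
  }
  tch <- par_of(spec$change$temp)
  tsch <- par_of(spec$change$temp_seasonality)
  pch <- par_of(spec$change$prec)
  psch <- par_of(spec$change$prec_seasonality)
  if (spec$change$prec$kind == "shift" && spec$change$prec$delta < -min(pbar)) {
    stop("requested precipitation shift would drive all months negative in ",
         "some cells", call. = FALSE)
  }

  pres <- build(0, 1, 0, 1)
  fut <- build(tch[1], tsch[2], pch[1], psch[2])
  list(
    present = monthly_climate(pres$tmin, pres$tmax, pres$prec, gs, "present"),
    future = monthly_climate(fut$tmin, fut$tmax, fut$prec, gs, "future")
  )
}

# Evaluate a species_response on a predictor stack -> probability matrix.
true_suitability <- function(resp, predictors) {
  gs <- predictors$spec
  if (resp$family == "uniform") {
    p <- matrix(resp$pmax, gs$nrow, gs$ncol)
  } else {
    x <- predictors$layers[[resp$var]]
    if (is.null(x)) {
      stop("response driver '", resp$var, "' not in predictor stack",
           call. = FALSE)
    }
    p <- switch(resp$family,
      gaussian = resp$pmax * exp(-((x - resp$center)^2) / (2 * resp$width^2)),
      logistic = resp$pmax * stats::plogis((x - resp$center) / resp$width)
    )
  }
  p[!predictors$mask] <- NA_real_
  p
}

#' Generate species occurrence records with known ground truth
#'
#' For each species in the scenario, draws `n_records` raw sightings from
#' the valid cells with probability proportional to the species' true
#' response evaluated on the supplied (present-day) predictors, then
#' deduplicates to one presence entry per cell. Record coordinates are the
#' centres of the sampled cells. The true suitability grids are returned in
#' a separate `truth` registry that the fitting code never sees.
#'
#' @param spec a [scenario_spec()].
#' @param predictors a [predictor_stack()] computed on the present climate.
#' @return List with `occurrences` (named list of `occurrence_set`),
#'   `records` (data.frame `species`, `x`, `y` of raw sightings) and
#'   `truth` (named list of true-suitability matrices with the response
#'   definition attached as attribute `"response"`).
#' @export
generate_species <- function(spec, predictors) {
  stopifnot(inherits(spec, "scenario_spec"),
            inherits(predictors, "predictor_stack"))
  set.seed(spec$seed + 1L)
  gs <- predictors$spec
  centers <- cell_centers(gs)
  valid <- which(predictors$mask)
  occurrences <- list()
  truth <- list()
  records <- list()
  for (resp in spec$species) {
    suit <- true_suitability(resp, predictors)
    w <- suit[valid]
    nz <- sum(w > 0, na.rm = TRUE)
    if (nz < resp$n_records && nz < length(valid)) {
      # with replacement the draw itself always succeeds; flag the case the
      # caller asked for more support than the response can ever provide
      if (nz == 0) {
        stop("species '", resp$name, "' has zero probability everywhere",
             call. = FALSE)
      }
    }
    cells <- valid[sample.int(length(valid), resp$n_records, replace = TRUE,
                              prob = w)]
    tab <- table(cells)
    occ_cells <- as.integer(names(tab))
    ord <- order(occ_cells)
    occurrences[[resp$name]] <- occurrence_set(
      species = resp$name,
      cells = occ_cells[ord],
      counts = as.integer(tab)[ord],
      spec = gs
    )
    attr(suit, "response") <- resp
    truth[[resp$name]] <- suit
    records[[resp$name]] <- data.frame(
      species = resp$name,
      x = centers[cells, "x"],
      y = centers[cells, "y"]
    )
  }
  list(
    occurrences = occurrences,
    records = do.call(rbind, c(records, list(make.row.names = FALSE))),
    truth = truth
  )
}

#' Generate a synthetic crop-extent grid
#'
#' Selects `round(crop_fraction * n_valid_cells)` cells, preferring cells
#' where the crop's true climatic suitability is high, and distributes
#' `crop_total_ha` hectares among them proportionally to suitability (plus
#' a small floor so every selected cell gets a positive extent). The total
#' allocated extent equals the requested total exactly.
#'
#' @param spec a [scenario_spec()].
#' @param predictors a [predictor_stack()] on the present climate.
#' @return List with `extent` (matrix of hectares per cell, 0 where no
#'   crop, `NA` off-mask) and `truth` (the crop's true-suitability matrix).
#' @export
generate_crop_extent <- function(spec, predictors) {
  stopifnot(inherits(spec, "scenario_spec"),
            inherits(predictors, "predictor_stack"))
  set.seed(spec$seed + 2L)
  gs <- predictors$spec
  suit <- true_suitability(spec$crop, predictors)
  valid <- which(predictors$mask)
  k <- round(spec$crop_fraction * length(valid))
  extent <- matrix(0, gs$nrow, gs$ncol)
  extent[!predictors$mask] <- NA_real_
  if (k > 0) {
    w <- suit[valid] + 0.02 * max(suit[valid], na.rm = TRUE)
    cells <- valid[sample.int(length(valid), k, prob = w)]
    share <- suit[cells] + 0.05
    extent[cells] <- spec$crop_total_ha * share / sum(share)
  }
  list(extent = extent, truth = suit)
}

#' Generate a complete synthetic scenario
#'
#' One-call wrapper: climate pair, present-day predictors (Bio01..Bio19 +
#' GDD5), species occurrences with truth registry, and crop extent.
#'
#' @param spec a [scenario_spec()].
#' @return List with `spec`, `climate` (present/future pair), `predictors`
#'   (present), `predictors_future`, `species` (see [generate_species()])
#'   and `crop` (see [generate_crop_extent()]).
#' @export
generate_scenario <- function(spec = scenario_spec()) {
  climate <- generate_climate(spec)
  predictors <- compute_predictors(climate$present)
  predictors_future <- compute_predictors(climate$future)
  species <- generate_species(spec, predictors)
  crop <- generate_crop_extent(spec, predictors)
  list(spec = spec, climate = climate, predictors = predictors,
       predictors_future = predictors_future, species = species, crop = crop)
}
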