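#' Pollinator availability index over crop cells
#'
#' Aggregates per-species ensemble suitability into a relative index of the
#' pollination service available to a crop: for crop cell `m`,
#' `PA_m = (1/S) * sum_s p_sm`, where `p_sm` is species `s`'s ensemble mean
#' probability of occurrence inside its agreement-masked presence area and
#' 0 outside, and `S` is the number of pollinator species. All species are
#' weighted equally (assumed equally efficient pollinators) and no
#' neighbourhood/foraging-distance term is applied, the model resolution
#' being coarser than typical foraging distances. PA is bounded in
#' `[0, 1]`; PA = 0 marks cells where every species is ensemble-absent.
#'
#' @param ensembles list of `ensemble_map` objects (one per species), all
#'   on one grid.
#' @param crop_mask logical matrix marking cells with crop presence
#'   (observed or predicted).
#' @param denominator optional alternative divisor (defaults to the number
#'   of species, the equal-efficiency form).
#' @return A `service_map`: `pa` (matrix, `NA` off the crop mask),
#'   `crop_mask`, `n_species`, `spec`, `scenario` (tag, default `""`).
#' @export
pollinator_availability <- function(ensembles, crop_mask,
                                    denominator = NULL) {
  if (!length(ensembles)) stop("empty species list", call. = FALSE)
  spec <- ensembles[[1]]$spec
  stopifnot(is.matrix(crop_mask), nrow(crop_mask) == spec$nrow,
            ncol(crop_mask) == spec$ncol)
  S <- length(ensembles)
  if (is.null(denominator)) denominator <- S
  total <- matrix(0, spec$nrow, spec$ncol)
  for (e in ensembles) {
    stopifnot(inherits(e, "ensemble_map"))
    stop_if_grid_mismatch(spec, e$spec, "species ensembles")
    ep <- e$effective_p
    ep[is.na(ep)] <- 0
    total <- total + ep
  }
  pa <- total / denominator
  pa[!crop_mask | is.na(crop_mask)] <- NA_real_
  structure(
    list(pa = pa, crop_mask = crop_mask & !is.na(crop_mask),
         n_species = S, spec = spec, scenario = ""),
    class = "service_map"
  )
}

#' @export
print.service_map <- function(x, ...) {
  v <- x$pa[!is.na(x$pa)]
  cat(sprintf(
    "<service_map>%s %d crop cells, %d species; PA range [%.3f, %.3f], %.1f%% at 0\n",
    if (nzchar(x$scenario)) paste0(" [", x$scenario, "]") else "",
    length(v), x$n_species, min(v), max(v), 100 * mean(v == 0)
  ))
  invisible(x)
}

#' Species richness from ensemble presence maps
#'
#' @param ensembles list of `ensemble_map` objects on one grid.
#' @return Matrix of per-cell species counts (ensemble presences).
#' @export
richness <- function(ensembles) {
  if (!length(ensembles)) stop("empty species list", call. = FALSE)
  spec <- ensembles[[1]]$spec
  sr <- matrix(0L, spec$nrow, spec$ncol)
  for (e in ensembles) {
    stop_if_grid_mismatch(spec, e$spec, "species ensembles")
    sr <- sr + e$presence
  }
  sr
}

#' Change in species richness between two periods
#'
#' @param present,future lists of `ensemble_map` objects for the same
#'   species set (matched by name/order) in each period.
#' @return Signed matrix `SR_future - SR_present`.
#' @export
richness_change <- function(present, future) {
  if (length(present) != length(future)) {
    stop("species sets differ between periods", call. = FALSE)
  }
  np <- vapply(present, function(e) as.character(e$species), character(1))
  nf <- vapply(future, function(e) as.character(e$species), character(1))
  if (!identical(np, nf)) {
    stop("species sets differ between periods", call. = FALSE)
  }
  richness(future) - richness(present)
}

#' Percent range change between two ensembles
#'
#' `100 * (area_future - area_present) / area_present`, the per-species
#' range change under a universal-expansion hypothesis (no dispersal
#' barriers); negative values are contractions.
#'
#' @param present,future `ensemble_map` objects for one species.
#' @return Percent change (scalar).
#' @export
range_change <- function(present, future) {
  stopifnot(inherits(present, "ensemble_map"), inherits(future, "ensemble_map"))
  stop_if_grid_mismatch(present$spec, future$spec, "ensembles")
  a0 <- sum(present$presence, na.rm = TRUE)
  a1 <- sum(future$presence, na.rm = TRUE)
  if (a0 == 0) {
    warning("empty present range: percent change undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * (a1 - a0) / a0
}

#' Frequency distribution of pollinator-availability classes
#'
#' Bins the PA values of a service map into classes and reports the percent
#' frequency of crop cells per class. PA = 0 (no pollinator predicted) is
#' always its own class; positive values fall into left-open intervals
#' `(edge_i, edge_{i+1}]`.
#'
#' @param service a `service_map`.
#' @param edges increasing breakpoints for the positive classes; the last
#'   edge must be >= 1 so the classes cover `[0, 1]`. Default mirrors the
#'   map classes used throughout the package's summaries.
#' @return data.frame `class`, `n_cells`, `share_pct` (sums to 100).
#' @export
pa_class_histogram <- function(service,
                               edges = c(0, 0.05, 0.2, 0.35, 0.5, 0.8, 1)) {
  stopifnot(inherits(service, "service_map"))
  stopifnot(all(diff(edges) > 0), edges[1] == 0, edges[length(edges)] >= 1)
  v <- service$pa[!is.na(service$pa)]
  if (!length(v)) stop("empty crop mask", call. = FALSE)
  zero <- v == 0
  pos <- cut(v[!zero], breaks = edges, include.lowest = FALSE)
  classes <- c("0", levels(pos))
  counts <- c(sum(zero), as.integer(table(pos)))
  data.frame(
    class = classes, n_cells = counts,
    share_pct = 100 * counts / length(v), row.names = NULL
  )
}

#' Pollinator availability under the three study scenarios
#'
#' Computes the service map for (A) the baseline: present-day pollinators
#' over observed crop cells; (B) the projected system: future pollinators
#' over the cells predicted suitable for the crop under the future climate
#' (the crop ensemble's agreement area); and (C) the persistence case:
#' future pollinators over today's crop cells, i.e. assuming the crop stays
#' where it is while the climate changes.
#'
#' @param pollinators_present,pollinators_future lists of `ensemble_map`
#'   objects per species.
#' @param crop_mask_present logical matrix of observed crop cells.
#' @param crop_ensemble_future the crop's future `ensemble_map` (scenario B
#'   uses its presence area).
#' @return Named list of `service_map`s: `baseline`, `future_crop_areas`,
#'   `future_climate_current_crop`.
#' @export
scenario_suite <- function(pollinators_present, pollinators_future,
                           crop_mask_present, crop_ensemble_future) {
  stopifnot(inherits(crop_ensemble_future, "ensemble_map"))
  a <- pollinator_availability(pollinators_present, crop_mask_present)
  a$scenario <- "baseline"
  future_mask <- crop_ensemble_future$presence
  if (!any(future_mask, na.rm = TRUE)) {
    warning("future crop ensemble predicts no presence anywhere",
            call. = FALSE)
  }
  b <- pollinator_availability(pollinators_future, future_mask)
  b$scenario <- "future-crop-areas"
  c_ <- pollinator_availability(pollinators_future, crop_mask_present)
  c_$scenario <- "future-climate-current-crop"
  list(baseline = a, future_crop_areas = b,
       future_climate_current_crop = c_)
}
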