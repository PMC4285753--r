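#' Compute the 19 bioclimatic variables
#'
#' Derives the standard bioclimatic summaries Bio01..Bio19 from a monthly
#' climate stack, following the ANUCLIM/WorldClim definitions. "Quarters"
#' are rolling windows of three consecutive calendar months, with
#' December-January wrap-around; the wettest/driest/warmest/coldest quarter
#' is chosen by the maximum or minimum of the relevant 3-month aggregate,
#' with ties broken by the earliest starting month, so the computation is
#' fully deterministic.
#'
#' Definitions used (Tmean = (tmin + tmax)/2 per month):
#' \describe{
#'   \item{Bio01}{annual mean of Tmean}
#'   \item{Bio02}{mean diurnal range, mean of (tmax - tmin)}
#'   \item{Bio03}{isothermality, 100 * Bio02 / Bio07}
#'   \item{Bio04}{temperature seasonality, 100 * SD of the 12 monthly Tmean
#'     (population SD, dividing by 12)}
#'   \item{Bio05/Bio06}{max of monthly tmax / min of monthly tmin}
#'   \item{Bio07}{temperature annual range, Bio05 - Bio06}
#'   \item{Bio08/Bio09}{mean Tmean of the wettest / driest quarter}
#'   \item{Bio10/Bio11}{mean Tmean of the warmest / coldest quarter}
#'   \item{Bio12}{annual precipitation (sum)}
#'   \item{Bio13/Bio14}{precipitation of the wettest / driest month}
#'   \item{Bio15}{precipitation seasonality, 100 * population SD / mean of
#'     monthly precipitation (0 where the mean is below `eps`)}
#'   \item{Bio16/Bio17}{precipitation of the wettest / driest quarter}
#'   \item{Bio18/Bio19}{precipitation of the warmest / coldest quarter}
#' }
#'
#' Bio03 is reported as `NA` where the annual range Bio07 is zero (a site
#' with no seasonal signal has undefined isothermality).
#'
#' @param mc a [monthly_climate()].
#' @param eps guard for the Bio15 coefficient of variation: cells whose mean
#'   monthly precipitation is below `eps` get Bio15 = 0.
#' @return A [predictor_stack()] with layers `Bio01`..`Bio19`.
#' @examples
#' mc <- constant_climate(grid_spec(2, 2), tmin = 5, tmax = 15, prec = 50)
#' compute_bioclim(mc)$layers$Bio03[1, 1]  # 100: diurnal == annual range
#' @export
compute_bioclim <- function(mc, eps = 1e-12) {
  stopifnot(inherits(mc, "monthly_climate"))
  nc <- n_cells(mc$spec)
  tmin <- matrix(mc$tmin, nc, 12)
  tmax <- matrix(mc$tmax, nc, 12)
  prec <- matrix(mc$prec, nc, 12)
  tavg <- (tmin + tmax) / 2

  pop_sd <- function(m) {
    mu <- rowMeans(m)
    sqrt(rowMeans((m - mu)^2))
  }
  # rolling 3-month aggregates, window q starts at month q (Dec-Jan wrap)
  roll3 <- function(m, fun = rowSums) {
    vapply(1:12, function(q) {
      idx <- ((q - 1):(q + 1)) %% 12 + 1
      fun(m[, idx, drop = FALSE])
    }, numeric(nrow(m)))
  }
  qprec <- roll3(prec, rowSums)        # quarter precipitation totals
  qtemp <- roll3(tavg, rowMeans)       # quarter mean temperatures
  # which.max/min over columns with first-index (earliest month) tie-break
  arg_first <- function(m, max = TRUE) {
    if (max) max.col(m, ties.method = "first")
    else max.col(-m, ties.method = "first")
  }
  pick <- function(values, sel) values[cbind(seq_len(nrow(values)), sel)]

  wettest <- arg_first(qprec, TRUE)
  driest  <- arg_first(qprec, FALSE)
  warmest <- arg_first(qtemp, TRUE)
  coldest <- arg_first(qtemp, FALSE)

  b <- list()
  b$Bio01 <- rowMeans(tavg)
  b$Bio02 <- rowMeans(tmax - tmin)
  b$Bio04 <- 100 * pop_sd(tavg)
  b$Bio05 <- apply(tmax, 1, max)
  b$Bio06 <- apply(tmin, 1, min)
  b$Bio07 <- b$Bio05 - b$Bio06
  b$Bio03 <- ifelse(b$Bio07 > 0, 100 * b$Bio02 / b$Bio07, NA_real_)
  b$Bio08 <- pick(qtemp, wettest)
  b$Bio09 <- pick(qtemp, driest)
  b$Bio10 <- pick(qtemp, warmest)
  b$Bio11 <- pick(qtemp, coldest)
  b$Bio12 <- rowSums(prec)
  b$Bio13 <- apply(prec, 1, max)
  b$Bio14 <- apply(prec, 1, min)
  pmu <- rowMeans(prec)
  b$Bio15 <- ifelse(pmu > eps, 100 * pop_sd(prec) / pmu, 0)
  b$Bio16 <- pick(qprec, wettest)
  b$Bio17 <- pick(qprec, driest)
  b$Bio18 <- pick(qprec, warmest)
  b$Bio19 <- pick(qprec, coldest)

  ord <- sprintf("Bio%02d", 1:19)
  layers <- lapply(b[ord], function(v) {
    matrix(v, mc$spec$nrow, mc$spec$ncol)
  })
  for (nm in ord) layers[[nm]][!mc$mask] <- NA_real_
  predictor_stack(layers, mc$spec, mask = mc$mask)
}

#' Growing degree days above 5 degrees C
#'
#' Accumulated thermal time relevant to fruit-tree development:
#' `GDD5 = sum over months of max(0, Tmean_m - 5) * days_in_month`, with
#' `Tmean_m = (tmin_m + tmax_m)/2` and a non-leap calendar. This is the
#' monthly approximation (each day of a month is assigned the month's mean
#' temperature); units are degree-days.
#'
#' @param mc a [monthly_climate()].
#' @param base base temperature in degrees C (default 5).
#' @return A matrix on the climate grid (`NA` outside the valid mask).
#' @examples
#' mc <- constant_climate(grid_spec(2, 2), tmin = 10, tmax = 20, prec = 50)
#' compute_gdd5(mc)[1, 1]  # Tmean 15 all year -> 10 * 365 = 3650
#' @export
compute_gdd5 <- function(mc, base = 5) {
  stopifnot(inherits(mc, "monthly_climate"))
  dim_days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  nc <- n_cells(mc$spec)
  tavg <- (matrix(mc$tmin, nc, 12) + matrix(mc$tmax, nc, 12)) / 2
  gdd <- as.vector(pmax(tavg - base, 0) %*% dim_days)
  out <- matrix(gdd, mc$spec$nrow, mc$spec$ncol)
  out[!mc$mask] <- NA_real_
  out
}

#' Bioclimatic predictors plus GDD5 in one stack
#'
#' Convenience wrapper: [compute_bioclim()] with a `GDD5` layer appended.
#'
#' @inheritParams compute_bioclim
#' @return A [predictor_stack()] with layers `Bio01`..`Bio19`, `GDD5`.
#' @export
compute_predictors <- function(mc) {
  ps <- compute_bioclim(mc)
  ps$layers$GDD5 <- compute_gdd5(mc)
  predictor_stack(ps$layers, ps$spec, ps$mask)
}

#' A spatially constant monthly climate
#'
#' Small helper mostly used in examples and sanity checks: every cell and
#' month gets the same tmin/tmax/prec (each may also be a length-12 vector
#' giving a seasonal cycle).
#'
#' @param spec a [grid_spec()].
#' @param tmin,tmax,prec scalars or length-12 monthly vectors.
#' @param period period label.
#' @return A [monthly_climate()].
#' @export
constant_climate <- function(spec, tmin, tmax, prec, period = "present") {
  expand <- function(v) {
    v <- rep_len(v, 12)
    a <- array(0, c(spec$nrow, spec$ncol, 12))
    for (m in 1:12) a[, , m] <- v[m]
    a
  }
  monthly_climate(expand(tmin), expand(tmax), expand(prec), spec, period)
}
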