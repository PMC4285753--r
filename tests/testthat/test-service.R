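test_that("pollinator availability is the equal-weight species mean", {
  p0 <- matrix(0.2, 4, 4)
  ens <- list(
    fake_ensemble(matrix(0.2, 4, 4), species = "s1"),
    fake_ensemble(matrix(0.4, 4, 4), species = "s2"),
    fake_ensemble(matrix(0, 4, 4), presence = matrix(FALSE, 4, 4),
                  species = "s3"),
    fake_ensemble(matrix(0.2, 4, 4), species = "s4")
  )
  crop <- matrix(TRUE, 4, 4)
  sm <- pollinator_availability(ens, crop)
  expect_equal(sm$pa, matrix(0.2, 4, 4))
  # all species at p = 1 -> PA = 1; all absent -> PA = 0
  ones <- replicate(3, fake_ensemble(matrix(1, 2, 2)), simplify = FALSE)
  expect_equal(pollinator_availability(ones, matrix(TRUE, 2, 2))$pa,
               matrix(1, 2, 2))
  absent <- replicate(3,
                      fake_ensemble(matrix(0.5, 2, 2),
                                    presence = matrix(FALSE, 2, 2)),
                      simplify = FALSE)
  expect_equal(pollinator_availability(absent, matrix(TRUE, 2, 2))$pa,
               matrix(0, 2, 2))
  expect_error(pollinator_availability(list(), crop), "empty")
})

test_that("PA obeys the mean-composition identity and monotonicity", {
  set.seed(80)
  ens <- lapply(1:5, function(i) {
    fake_ensemble(matrix(runif(36), 6, 6), species = paste0("s", i))
  })
  crop <- matrix(TRUE, 6, 6)
  pa_old <- pollinator_availability(ens, crop)$pa
  zero_sp <- fake_ensemble(matrix(0.7, 6, 6),
                           presence = matrix(FALSE, 6, 6), species = "z")
  pa_new <- pollinator_availability(c(ens, list(zero_sp)), crop)$pa
  expect_equal(pa_new, pa_old * 5 / 6, tolerance = 1e-12)
  # permutation invariance over species
  pa_perm <- pollinator_availability(ens[c(3, 1, 5, 2, 4)], crop)$pa
  expect_equal(pa_perm, pa_old, tolerance = 1e-12)
  # raising one species' p never lowers PA
  ens2 <- ens
  ens2[[2]]$effective_p <- pmin(ens2[[2]]$effective_p + 0.1, 1)
  pa_up <- pollinator_availability(ens2, crop)$pa
  expect_true(all(pa_up >= pa_old - 1e-12))
  expect_true(all(pa_old >= 0 & pa_old <= 1))
})

test_that("richness counts and change maps follow the binary stacks", {
  set.seed(81)
  mk <- function() {
    pres <- matrix(runif(25) > 0.5, 5, 5)
    fake_ensemble(matrix(runif(25), 5, 5), presence = pres,
                  species = "s")
  }
  ens <- replicate(4, mk(), simplify = FALSE)
  for (i in seq_along(ens)) ens[[i]]$species <- paste0("s", i)
  sr <- richness(ens)
  want <- Reduce(`+`, lapply(ens, function(e) e$presence + 0L))
  expect_equal(sr, want, ignore_attr = TRUE)
  # one species gains one cell
  fut <- ens
  gain_cell <- which(!fut[[1]]$presence)[1]
  fut[[1]]$presence[gain_cell] <- TRUE
  ch <- richness_change(ens, fut)
  expect_equal(ch[gain_cell], 1L)
  expect_equal(sum(ch != 0), 1L)
  # species sets must match between periods
  expect_error(richness_change(ens, ens[1:2]), "differ")
  bad <- fut; bad[[1]]$species <- "other"
  expect_error(richness_change(ens, bad), "differ")
})

test_that("range change is the percent difference in presence area", {
  a <- fake_ensemble(matrix(0.5, 4, 4),
                     presence = matrix(rep(c(TRUE, FALSE), 8), 4, 4))
  same <- a
  expect_equal(range_change(a, same), 0)
  empty <- fake_ensemble(matrix(0, 4, 4), presence = matrix(FALSE, 4, 4))
  expect_equal(range_change(a, empty), -100)
  dbl <- fake_ensemble(matrix(0.5, 4, 4), presence = matrix(TRUE, 4, 4))
  expect_equal(range_change(a, dbl), 100)
  expect_warning(rc <- range_change(empty, a), "empty present range")
  expect_true(is.na(rc))
})

test_that("PA class histograms bin correctly and close to 100%", {
  p <- matrix(NA_real_, 5, 5)
  p[1:20] <- c(rep(0, 5), rep(0.1, 10), rep(0.4, 5))
  sm <- structure(list(pa = p, crop_mask = !is.na(p), n_species = 3,
                       spec = grid_spec(5, 5), scenario = "t"),
                  class = "service_map")
  tab <- pa_class_histogram(sm)
  expect_equal(sum(tab$share_pct), 100, tolerance = 1e-9)
  expect_equal(tab$share_pct[tab$class == "0"], 25)
  expect_equal(tab$n_cells[tab$class == "(0.05,0.2]"], 10L)
  expect_equal(tab$n_cells[tab$class == "(0.35,0.5]"], 5L)
  # all-zero and single-value degenerate cases
  pz <- matrix(0, 3, 3)
  smz <- structure(list(pa = pz, crop_mask = matrix(TRUE, 3, 3),
                        n_species = 1, spec = grid_spec(3, 3),
                        scenario = ""), class = "service_map")
  tz <- pa_class_histogram(smz)
  expect_equal(tz$share_pct[tz$class == "0"], 100)
  pu <- matrix(0.1, 3, 3)
  smu <- structure(list(pa = pu, crop_mask = matrix(TRUE, 3, 3),
                        n_species = 1, spec = grid_spec(3, 3),
                        scenario = ""), class = "service_map")
  tu <- pa_class_histogram(smu)
  expect_equal(max(tu$share_pct), 100)
  # random values match brute-force binning
  set.seed(82)
  pr <- matrix(runif(25), 5, 5)
  smr <- structure(list(pa = pr, crop_mask = matrix(TRUE, 5, 5),
                        n_species = 1, spec = grid_spec(5, 5),
                        scenario = ""), class = "service_map")
  edges <- c(0, 0.05, 0.2, 0.35, 0.5, 0.8, 1)
  tr <- pa_class_histogram(smr, edges)
  brute <- sapply(seq_len(length(edges) - 1), function(i) {
    sum(pr > edges[i] & pr <= edges[i + 1])
  })
  expect_equal(tr$n_cells, c(sum(pr == 0), brute))
})

test_that("the three service scenarios use the right masks and maps", {
  set.seed(83)
  pres_ens <- lapply(1:3, function(i) {
    fake_ensemble(matrix(runif(16), 4, 4), species = paste0("s", i))
  })
  crop_now <- matrix(FALSE, 4, 4); crop_now[c(1, 6, 11)] <- TRUE
  crop_fut <- fake_ensemble(matrix(0.6, 4, 4),
                            presence = matrix(c(TRUE, FALSE), 4, 4))
  # identical present/future pollinators: scenarios A and C coincide
  suite <- scenario_suite(pres_ens, pres_ens, crop_now, crop_fut)
  expect_equal(suite$baseline$pa, suite$future_climate_current_crop$pa)
  expect_equal(suite$future_crop_areas$crop_mask, crop_fut$presence)
  # an empty future crop triggers a warning
  empty_crop <- fake_ensemble(matrix(0, 4, 4),
                              presence = matrix(FALSE, 4, 4))
  expect_warning(scenario_suite(pres_ens, pres_ens, crop_now, empty_crop),
                 "no presence")
  # a constructed northward shift lowers PA on a southern crop belt
  north_p <- matrix(0, 8, 8); north_p[1:2, ] <- 0.8   # rows 1-2 = north
  south_p <- matrix(0, 8, 8); south_p[7:8, ] <- 0.8
  south_crop <- matrix(FALSE, 8, 8); south_crop[7:8, ] <- TRUE
  now <- list(fake_ensemble(south_p))
  fut <- list(fake_ensemble(north_p))
  crop_fut8 <- fake_ensemble(matrix(0.6, 8, 8),
                             presence = matrix(TRUE, 8, 8))
  suite2 <- scenario_suite(now, fut, south_crop, crop_fut8)
  expect_gt(mean(suite2$baseline$pa, na.rm = TRUE),
            mean(suite2$future_climate_current_crop$pa, na.rm = TRUE))
})
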