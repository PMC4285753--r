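test_that("the generator is bit-identical under a fixed seed", {
  s1 <- generate_scenario(tiny_scenario(seed = 9))
  s2 <- generate_scenario(tiny_scenario(seed = 9))
  expect_identical(s1$climate$present$tmin, s2$climate$present$tmin)
  expect_identical(s1$climate$future$prec, s2$climate$future$prec)
  expect_identical(s1$species$records, s2$species$records)
  expect_identical(s1$crop$extent, s2$crop$extent)
})

test_that("all-none change patterns give an identical future stack", {
  sc <- tiny_scenario(seed = 4, change = list(
    temp = change_none(), temp_seasonality = change_none(),
    prec = change_none(), prec_seasonality = change_none()
  ))
  cl <- generate_climate(sc)
  expect_identical(cl$present$tmin, cl$future$tmin)
  expect_identical(cl$present$tmax, cl$future$tmax)
  expect_identical(cl$present$prec, cl$future$prec)
})

test_that("a temperature shift moves monthly means by exactly its delta", {
  sc <- tiny_scenario(seed = 5, change = list(temp = change_shift(2)))
  cl <- generate_climate(sc)
  d <- ((cl$future$tmin + cl$future$tmax) -
          (cl$present$tmin + cl$present$tmax)) / 2
  expect_equal(mean(d), 2, tolerance = 1e-12)
  expect_equal(range(d), c(2, 2), tolerance = 1e-12)
})

test_that("a seasonality reshape scales Bio04 by the requested factor", {
  sc <- tiny_scenario(seed = 6, change = list(
    temp_seasonality = change_reshape(scale = 2)
  ))
  cl <- generate_climate(sc)
  b_now <- compute_bioclim(cl$present)$layers$Bio04
  b_fut <- compute_bioclim(cl$future)$layers$Bio04
  expect_equal(b_fut, 2 * b_now, tolerance = 1e-9)
})

test_that("generated climate satisfies its physical invariants", {
  cl <- generate_climate(tiny_scenario(seed = 7))
  for (period in cl) {
    expect_true(all(period$tmax >= period$tmin))
    expect_true(all(period$prec >= 0))
  }
})

test_that("uniform-response occurrences are spatially uniform", {
  # pool raw records from 20 seeds and test quadrant counts against a
  # uniform multinomial
  counts <- matrix(0, 2, 2)
  for (seed in 1:20) {
    sc <- tiny_scenario(seed = seed, species = list(
      species_response("flat", family = "uniform", pmax = 0.5,
                       n_records = 100)
    ))
    scn <- generate_species(sc, compute_predictors(generate_climate(sc)$present))
    gs <- sc$grid
    r <- scn$records
    counts[1, 1] <- counts[1, 1] + sum(r$x < 50000 & r$y < 50000)
    counts[1, 2] <- counts[1, 2] + sum(r$x < 50000 & r$y >= 50000)
    counts[2, 1] <- counts[2, 1] + sum(r$x >= 50000 & r$y < 50000)
    counts[2, 2] <- counts[2, 2] + sum(r$x >= 50000 & r$y >= 50000)
  }
  gof <- stats::chisq.test(as.vector(counts), p = rep(1 / 4, 4))
  expect_gt(gof$p.value, 0.01)
})

test_that("a degenerate single-cell response collapses to one presence", {
  sc <- tiny_scenario(seed = 8)
  preds <- compute_predictors(generate_climate(sc)$present)
  # response positive in exactly one cell: a delta bump on Bio01
  target_cell <- 137L
  x0 <- preds$layers$Bio01[target_cell]
  one_hot <- ifelse(abs(preds$layers$Bio01 - x0) < 1e-12, 1, 0)
  preds2 <- predictor_stack(c(preds$layers, list(onehot = one_hot)),
                            preds$spec)
  sc2 <- tiny_scenario(seed = 8, species = list(
    species_response("point", var = "onehot", family = "logistic",
                     center = 0.5, width = 0.01, pmax = 1, n_records = 50)
  ))
  out <- generate_species(sc2, preds2)
  occ <- out$occurrences$point
  expect_equal(length(occ$cells), 1L)
  expect_equal(occ$cells, target_cell)
  expect_equal(sum(occ$counts), 50L)
})

test_that("record counts land in the study's per-species range", {
  sc <- tiny_scenario(seed = 10, species = list(
    species_response("few", family = "uniform", pmax = 0.3, n_records = 26),
    species_response("many", family = "uniform", pmax = 0.3, n_records = 2096)
  ))
  out <- generate_species(sc, compute_predictors(generate_climate(sc)$present))
  tallies <- vapply(out$occurrences, function(o) sum(o$counts), integer(1))
  expect_equal(unname(tallies), c(26L, 2096L))
})

test_that("crop extent hits the requested cell fraction and total area", {
  sc <- scenario_spec(grid = grid_spec(100, 100, cellsize = 5000), seed = 11,
                      crop_fraction = 0.14, crop_total_ha = 12200)
  preds <- compute_predictors(generate_climate(sc)$present)
  crop <- generate_crop_extent(sc, preds)
  n_occupied <- sum(crop$extent > 0, na.rm = TRUE)
  expect_true(abs(n_occupied - 1400) <= 50)
  expect_equal(sum(crop$extent, na.rm = TRUE), 12200, tolerance = 1e-9)
  expect_true(all(crop$extent[crop$extent > 0] > 0, na.rm = TRUE))
})

test_that("zero crop fraction yields an all-zero extent grid", {
  sc <- tiny_scenario(seed = 12, crop_fraction = 0)
  preds <- compute_predictors(generate_climate(sc)$present)
  crop <- generate_crop_extent(sc, preds)
  expect_true(all(crop$extent == 0, na.rm = TRUE))
})

test_that("the truth registry is kept apart from the occurrence data", {
  scn <- generate_scenario(tiny_scenario(seed = 13))
  # occurrence sets carry only cells/counts, never the truth surface
  expect_false(any(vapply(scn$species$occurrences, function(o) {
    any(grepl("truth|suit", names(o)))
  }, logical(1))))
  expect_true(all(names(scn$species$truth) %in%
                    names(scn$species$occurrences)))
})
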