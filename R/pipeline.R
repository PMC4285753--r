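#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis with its default:
#' the predictor subsets for the pollinator (PDM) and crop (ODM) models,
#' the resampling schemes and ensemble agreement rules, the collinearity
#' threshold, and the resampling budgets. Defaults encode the study design
#' this package implements: PDM = 10-fold cross-validation with a strict
#' all-10 agreement rule over predictors `{Bio03, Bio07, Bio09, Bio11,
#' Bio15, Bio19}`; ODM = ten 75/25 splits, hinge features only, 7-of-10
#' agreement over `{Bio04, Bio06, Bio08, Bio09, Bio18}`.
#'
#' @param scenario a [scenario_spec()] describing the synthetic inputs.
#' @param pdm_vars,odm_vars predictor layer names for the two model kinds.
#' @param pdm_scheme,odm_scheme resampling schemes.
#' @param pdm_min_agreement,odm_min_agreement ensemble agreement rules.
#' @param odm_classes feature classes for the crop model (hinge-only by
#'   default); the PDM uses automatic class selection by sample size.
#' @param lambda0 eigenvalue threshold for Jolliffe B2 selection.
#' @param run_selection run the B2 screen on the PDM predictor set and
#'   report it (the modelling still uses `pdm_vars`, mirroring a design in
#'   which the pollinator subset came from the screen and the crop subset
#'   from the literature)?
#' @param threshold_percentile training-presence threshold percentile.
#' @param n_boot bootstrap replicates for permutation importance.
#' @param n_resamples resamples for the extent-suitability correlation.
#' @param n_null null-model replicates per species (0 disables the null
#'   test, the most expensive stage).
#' @param background_n background sample size for the Maxent fits.
#' @param seed master seed; all stage seeds derive from it.
#' @param outdir output directory (created if missing).
#' @return A `run_config` list.
#' @export
run_config <- function(scenario = scenario_spec(),
                       pdm_vars = c("Bio03", "Bio07", "Bio09", "Bio11",
                                    "Bio15", "Bio19"),
                       odm_vars = c("Bio04", "Bio06", "Bio08", "Bio09",
                                    "Bio18"),
                       pdm_scheme = "cv10", odm_scheme = "split75x10",
                       pdm_min_agreement = 10L, odm_min_agreement = 7L,
                       odm_classes = "hinge",
                       lambda0 = 0.70, run_selection = TRUE,
                       threshold_percentile = 10,
                       n_boot = 10000L, n_resamples = 9999L, n_null = 0L,
                       background_n = 10000L,
                       seed = 1L, outdir = tempfile("pollavail_run_")) {
  structure(
    list(scenario = scenario, pdm_vars = pdm_vars, odm_vars = odm_vars,
         pdm_scheme = pdm_scheme, odm_scheme = odm_scheme,
         pdm_min_agreement = as.integer(pdm_min_agreement),
         odm_min_agreement = as.integer(odm_min_agreement),
         odm_classes = odm_classes, lambda0 = lambda0,
         run_selection = isTRUE(run_selection),
         threshold_percentile = threshold_percentile,
         n_boot = as.integer(n_boot), n_resamples = as.integer(n_resamples),
         n_null = as.integer(n_null),
         background_n = as.integer(background_n),
         seed = as.integer(seed), outdir = outdir),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar keys override [run_config()] defaults; the synthetic scenario is
#' configured through nested keys `scenario: {nrow, ncol, cellsize, seed,
#' crop_fraction, crop_total_ha}`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @examples
#' cfg <- read_run_config(
#'   system.file("extdata", "example_config.yaml", package = "pollavail")
#' )
#' cfg$scenario$grid
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- raw[setdiff(names(raw), "scenario")]
  if (!is.null(raw$scenario)) {
    sc <- raw$scenario
    args$scenario <- scenario_spec(
      grid = grid_spec(sc$nrow %||% 50, sc$ncol %||% 50,
                       cellsize = sc$cellsize %||% 5000),
      seed = sc$seed %||% 1,
      crop_fraction = sc$crop_fraction %||% 0.14,
      crop_total_ha = sc$crop_total_ha %||% 12200
    )
  }
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes the stages end to end on a synthetic scenario: climate
#' generation, bioclimatic predictors (+GDD5), optional collinearity
#' screen, per-species pollinator models and the crop model, permutation
#' importance, MESS/MoD between present and future predictor space,
#' species richness and range change, and the three pollinator-availability
#' scenarios. All artifacts are written to `config$outdir` as plain-text
#' rasters (ESRI ASCII) and CSV/JSON tables, and a manifest with MD5 hashes
#' and the effective configuration is returned and saved, so a rerun with
#' identical configuration reproduces identical hashes.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages?
#' @return The manifest (list with `files`, `config`, `summaries`),
#'   invisibly; side effect: files under `config$outdir`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(path) files <<- c(files, path)

  say("stage 1/7: synthetic scenario")
  scn <- generate_scenario(config$scenario)
  spec <- scn$spec$grid
  utils::write.csv(scn$species$records,
                   file.path(config$outdir, "records.csv"),
                   row.names = FALSE)
  emit(file.path(config$outdir, "records.csv"))

  say("stage 2/7: predictors")
  for (v in unique(c(config$pdm_vars, config$odm_vars))) {
    p <- file.path(config$outdir, paste0("present_", v, ".asc"))
    write_ascii_grid(scn$predictors$layers[[v]], spec, p); emit(p)
    p <- file.path(config$outdir, paste0("future_", v, ".asc"))
    write_ascii_grid(scn$predictors_future$layers[[v]], spec, p); emit(p)
  }

  selection <- NULL
  if (config$run_selection) {
    say("stage 3/7: collinearity screen (Jolliffe B2)")
    cand <- stack_matrix(scn$predictors,
                         vars = sprintf("Bio%02d", 1:19))
    selection <- jolliffe_b2(cand, lambda0 = config$lambda0)
    sel_path <- file.path(config$outdir, "selection.json")
    jsonlite::write_json(
      list(retained = selection$retained,
           rejected = selection$rejected,
           eigenvalues = selection$eigenvalues,
           lambda0 = selection$lambda0),
      sel_path, auto_unbox = TRUE, digits = NA
    )
    emit(sel_path)
  } else {
    say("stage 3/7: collinearity screen skipped")
  }

  say("stage 4/7: pollinator distribution models")
  mx_cfg <- maxent_config(background_n = config$background_n)
  pdm_runs <- list()
  pdm_present <- list()
  pdm_future <- list()
  importance <- list()
  for (sp in names(scn$species$occurrences)) {
    occ <- scn$species$occurrences[[sp]]
    rs <- resample_fit(scn$predictors, occ, scheme = config$pdm_scheme,
                       vars = config$pdm_vars, config = mx_cfg,
                       seed = config$seed + 10L)
    pdm_runs[[sp]] <- rs
    pdm_present[[sp]] <- ensemble(rs, config$pdm_min_agreement)
    pdm_future[[sp]] <- project_ensemble(rs, scn$predictors_future,
                                         config$pdm_min_agreement)
    imp <- permutation_importance(rs, scn$predictors,
                                  n_boot = config$n_boot,
                                  seed = config$seed + 20L)
    importance[[sp]] <- cbind(species = sp, imp$summary)
    p <- file.path(config$outdir, paste0("pdm_present_", sp, ".asc"))
    write_ascii_grid(pdm_present[[sp]]$effective_p, spec, p); emit(p)
    p <- file.path(config$outdir, paste0("pdm_future_", sp, ".asc"))
    write_ascii_grid(pdm_future[[sp]]$effective_p, spec, p); emit(p)
  }
  imp_path <- file.path(config$outdir, "importance.csv")
  utils::write.csv(do.call(rbind, importance), imp_path, row.names = FALSE)
  emit(imp_path)

  say("stage 5/7: crop distribution model")
  crop_cells <- which(!is.na(scn$crop$extent) & scn$crop$extent > 0)
  odm_cfg <- maxent_config(classes = config$odm_classes,
                           background_n = config$background_n)
  odm_runs <- resample_fit(scn$predictors, crop_cells,
                           scheme = config$odm_scheme,
                           vars = config$odm_vars, config = odm_cfg,
                           seed = config$seed + 30L)
  odm_present <- ensemble(odm_runs, config$odm_min_agreement)
  odm_future <- project_ensemble(odm_runs, scn$predictors_future,
                                 config$odm_min_agreement)
  p <- file.path(config$outdir, "odm_future_p.asc")
  write_ascii_grid(odm_future$effective_p, spec, p); emit(p)

  null_reports <- list()
  if (config$n_null > 0) {
    say("stage 5b: null models (%d replicates/species)", config$n_null)
    for (sp in names(scn$species$occurrences)) {
      occ <- scn$species$occurrences[[sp]]
      obs <- mean(vapply(pdm_runs[[sp]]$runs, `[[`, numeric(1), "test_auc"))
      null_reports[[sp]] <- null_model_test(
        length(occ$cells), scn$predictors, n_null = config$n_null,
        scheme = config$pdm_scheme, vars = config$pdm_vars,
        config = mx_cfg, observed_auc = obs, seed = config$seed + 40L
      )
    }
  }

  say("stage 6/7: environmental novelty (MESS)")
  pdm_ref <- stack_matrix(scn$predictors, vars = config$pdm_vars)
  odm_ref <- stack_matrix(scn$predictors, vars = config$odm_vars)
  mess_pdm <- mess(pdm_ref, scn$predictors_future[config$pdm_vars])
  mess_odm <- mess(odm_ref, scn$predictors_future[config$odm_vars])
  for (nm in c("pdm", "odm")) {
    mr <- if (nm == "pdm") mess_pdm else mess_odm
    p <- file.path(config$outdir, paste0("mess_", nm, ".asc"))
    write_ascii_grid(mr$mess, spec, p); emit(p)
    p <- file.path(config$outdir, paste0("mod_share_", nm, ".csv"))
    utils::write.csv(mod_summary(mr), p, row.names = FALSE); emit(p)
  }

  say("stage 7/7: pollinator availability")
  crop_mask <- !is.na(scn$crop$extent) & scn$crop$extent > 0
  scenarios <- scenario_suite(pdm_present, pdm_future, crop_mask, odm_future)
  hist_tabs <- list()
  for (nm in names(scenarios)) {
    p <- file.path(config$outdir, paste0("pa_", nm, ".asc"))
    write_ascii_grid(scenarios[[nm]]$pa, spec, p); emit(p)
    if (any(!is.na(scenarios[[nm]]$pa))) {
      hist_tabs[[nm]] <- cbind(scenario = nm,
                               pa_class_histogram(scenarios[[nm]]))
    }
  }
  p <- file.path(config$outdir, "pa_histogram.csv")
  utils::write.csv(do.call(rbind, hist_tabs), p, row.names = FALSE); emit(p)

  sr_present <- richness(pdm_present)
  sr_change <- richness_change(pdm_present, pdm_future)
  p <- file.path(config$outdir, "richness_present.asc")
  write_ascii_grid(sr_present + 0, spec, p); emit(p)
  p <- file.path(config$outdir, "richness_change.asc")
  write_ascii_grid(sr_change + 0, spec, p); emit(p)

  rng <- vapply(names(pdm_present), function(sp) {
    range_change(pdm_present[[sp]], pdm_future[[sp]])
  }, numeric(1))
  corr <- extent_probability_correlation(
    scn$crop$extent, odm_present$mean_p,
    n_resamples = config$n_resamples, seed = config$seed + 50L
  )

  summaries <- list(
    species = names(pdm_present),
    pdm_mean_test_auc = vapply(pdm_runs, function(rs) {
      mean(vapply(rs$runs, `[[`, numeric(1), "test_auc"))
    }, numeric(1)),
    odm_mean_test_auc = mean(vapply(odm_runs$runs, `[[`, numeric(1),
                                    "test_auc")),
    range_change_pct = rng,
    extent_correlation = corr,
    null_mean_auc = if (length(null_reports)) {
      vapply(null_reports, `[[`, numeric(1), "mean_null")
    },
    retained_predictors = if (!is.null(selection)) selection$retained
  )
  manifest <- list(
    created = format(t0, "%Y-%m-%dT%H:%M:%S"),
    config = config[setdiff(names(config), "scenario")],
    files = data.frame(
      path = basename(files),
      md5 = unname(tools::md5sum(files)),
      stringsAsFactors = FALSE
    ),
    summaries = summaries
  )
  jsonlite::write_json(
    manifest[c("config", "files", "summaries")],
    file.path(config$outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE
  )
  say("done in %.1f s; %d artifacts in %s",
      as.numeric(difftime(Sys.time(), t0, units = "secs")),
      length(files) + 1L, config$outdir)
  invisible(manifest)
}

#' Project a fitted run set onto new climate and re-ensemble
#'
#' Re-scores every run of a [resample_fit()] run set on a different
#' predictor stack (e.g. the future climate), keeping each run's training
#' threshold, and applies the agreement rule to the projected binary maps.
#'
#' @param run_set a `run_set`.
#' @param predictors the projection [predictor_stack()] (same variables).
#' @param min_agreement agreement rule for the projected ensemble.
#' @return An `ensemble_map` on the projection stack's grid.
#' @export
project_ensemble <- function(run_set, predictors, min_agreement) {
  stopifnot(inherits(run_set, "run_set"),
            inherits(predictors, "predictor_stack"))
  proj <- run_set
  proj$spec <- predictors$spec
  cells <- which(predictors$mask)
  X <- stack_matrix(predictors, cells, run_set$vars)
  for (r in seq_along(proj$runs)) {
    p_grid <- empty_layer(predictors$spec)
    p_grid[cells] <- predict(proj$runs[[r]]$model,
                             X[, names(proj$runs[[r]]$model$bounds$min),
                               drop = FALSE])
    proj$runs[[r]]$p <- p_grid
  }
  ensemble(proj, min_agreement)
}
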