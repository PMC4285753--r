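# pollavail

Climate-driven modelling of crop–pollinator spatial overlap.

`pollavail` is an R package for ecologists studying how climate change can
decouple an insect-pollinated crop from its wild pollinators. From gridded
monthly climate (tmin, tmax, precipitation) and presence-only species
records it:

* derives the 19 bioclimatic variables and growing degree days above 5 °C
  (`compute_bioclim()`, `compute_gdd5()`);
* reduces predictor collinearity with Jolliffe's PCA rejection method B2
  at an eigenvalue threshold λ₀ = 0.70 (`jolliffe_b2()`);
* fits presence-only maximum-entropy species distribution models (Maxent
  formulation: an L1-regularized Gibbs distribution over background cells,
  with linear/quadratic/hinge features), under 10-fold cross-validation
  for pollinators and ten 75/25 splits for the crop (`fit_maxent()`,
  `resample_fit()`);
* converts each run to a binary map at the 10th-percentile
  training-presence threshold and combines runs with an agreement rule —
  all 10 runs for wild pollinators, at least 7 of 10 for the managed crop
  (`threshold_10pct()`, `ensemble()`);
* evaluates models with rank-based AUC against null models of randomly
  placed pseudo-presences, and ranks predictors by the drop in test AUC
  after background permutation, with 10 000-replicate bootstrap intervals
  (`auc()`, `null_model_test()`, `permutation_importance()`);
* quantifies climatic novelty between training and projection conditions
  with multivariate environmental similarity surfaces and
  most-dissimilar-variable maps (`mess()`, `mod_summary()`);
* maps the relative pollinator availability index over crop cells,

  PA&#8201;<sub>m</sub> = (1/S) Σ<sub>s</sub> p<sub>sm</sub>,

  the equal-weight mean of the S species' effective ensemble
  probabilities of occurrence in cell m (0 outside a species' agreement
  area), for three scenarios: present pollinators × current crop, future
  pollinators × future predicted crop area, and future pollinators ×
  current crop (`pollinator_availability()`, `scenario_suite()`).

Real recording-scheme and climate-projection data are not redistributable,
so the package includes a seeded synthetic-data generator
(`generate_scenario()`) producing spatially autocorrelated monthly climate,
a future scenario built from three qualitative change patterns (none /
systematic shift / reshape of the distribution), species with known
responses to named predictors, and a sparse crop-extent grid — with the
ground truth kept in a registry the fitting code never reads. The methods
vignette (`vignettes/pollinator-availability-modelling.Rmd`) documents the
model, its assumptions and all numerical choices.

## A worked example

```r
library(pollavail)

cfg <- run_config(
  scenario = scenario_spec(grid = grid_spec(30, 30, cellsize = 5000),
                           seed = 7),
  n_boot = 1000, n_resamples = 999, seed = 7,
  outdir = "pollavail_demo"
)
manifest <- run_pipeline(cfg)

round(manifest$summaries$pdm_mean_test_auc, 3)
#>  sp_coldlim sp_rainseas  sp_uniform
#>       0.651       0.675       0.484
round(manifest$summaries$extent_correlation$rho, 3)
#> [1] 0.539
manifest$summaries$extent_correlation$p_value
#> [1] 0.001
```

The two structured synthetic species (a cold-limited one and one tied to
precipitation seasonality) fit clearly better than the no-signal control
(test AUC 0.65–0.68 versus 0.48, the latter indistinguishable from a null
model), and crop extent correlates positively with modelled suitability
(Spearman ρ = 0.54, significant against 999 random re-pairings) because
the generator places larger orchards in climatically better cells.
Permutation importance recovers each species' true driver: the largest
AUC drops are Bio15 (0.150) for the rain-seasonality species and Bio07
(0.107) for the cold-limited species.

The default future scenario is severe — +2 °C everywhere and doubled
temperature seasonality — so the projected predictor space largely leaves
the training range (strongly negative MESS): under the strict all-10
agreement rule every synthetic species loses its entire range
(`range_change_pct` = −100) and the scenario-C pollinator availability
collapses to 0 on all current crop cells, while the baseline scenario
spreads across the PA classes (32% of crop cells in (0.2, 0.35], 28% in
(0.35, 0.5], 4% with no pollinators). Milder scenarios are one
`change_shift()`/`change_reshape()` argument away.

All artifacts (ESRI ASCII rasters, CSV/JSON tables) land in `outdir`
together with a manifest of MD5 hashes; identical configuration and seeds
reproduce identical hashes.

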