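Package: pollavail
Title: Climate-Driven Modelling of Crop-Pollinator Spatial Overlap
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model climate-driven spatial mismatch between an
    insect-pollinated crop and its wild pollinators. Derives the 19
    bioclimatic variables and growing degree days above 5 degrees C from
    monthly climate grids, reduces predictor collinearity with Jolliffe's
    principal-component rejection method B2, fits presence-only
    maximum-entropy species distribution models with linear, quadratic and
    hinge features, evaluates them against null models with rank-based AUC
    and permutation importance, quantifies environmental novelty with
    multivariate environmental similarity surfaces (MESS), and maps a
    relative pollinator-availability index over crop cells for present and
    projected climates. Includes a fully seeded synthetic-data generator so
    the whole pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
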