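Package: srisoscape
Title: Bioavailable Strontium Isoscapes by Random Forest and Stacked Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and evaluation of bioavailable 87Sr/86Sr isoscapes
    from georeferenced sample databases and environmental covariate rasters.
    Provides covariate extraction with nearest-valid-cell fallback,
    correlation pruning, three-step forest-based variable selection,
    random-forest isoscape prediction with quantile-forest spatial
    uncertainty, a stacked-ensemble (super-learner) alternative with oblique
    geographic coordinates and spatial cross-validation, an incremental
    sampling-effort calibration experiment, and buffer-based local/non-local
    provenance assessment of archaeological samples. A synthetic-landscape
    generator with piecewise geology and autocorrelated climate fields makes
    every stage testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ranger,
    rpart,
    geosphere,
    glmnet,
    e1071,
    nnet,
    xgboost,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
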