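# Orchestration: one configuration object drives the full sequence
# extract -> prune -> select -> fit -> predict -> calibrate -> assess, with
# on-disk intermediates and a hashed artifact manifest so reruns are
# verifiable. Individual stages can be toggled off; stage inputs are never
# mutated by later stages.

#' Build and validate a pipeline configuration
#'
#' @param sample_table Path to the sample CSV (sm1 or synthetic schema).
#' @param covariate_dir Directory of `<name>.asc` covariate rasters named
#'   per [covariate_registry()] (extra rasters are allowed; non-registry
#'   names are an error).
#' @param out_dir Output directory (created on run).
#' @param site_table Optional path to an sm2-schema CSV for the provenance
#'   stage.
#' @param new_table Optional path to a second sample CSV (the "new
#'   regional" set) for the calibration stage.
#' @param sample_schema Schema of `sample_table`.
#' @param stages Character vector of stages to run, in fixed order.
#' @param seed Master seed; every random stage derives from it.
#' @param max_fallback_km Nearest-valid-cell search limit, km.
#' @param prune_threshold Correlation-pruning threshold.
#' @param n_trees Trees for the final forest.
#' @param selection Named list of [select_variables()] arguments.
#' @param cv Named list with `k` and `repeats` for [cross_validate()].
#' @param calibration Named list of [incremental_calibration()] arguments.
#' @param radii_km Assessment radii, km.
#' @param eml Logical: also fit the stacked ensemble and emit its product.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(sample_table, covariate_dir, out_dir,
                            site_table = NULL, new_table = NULL,
                            sample_schema = c("sm1", "synthetic"),
                            stages = c("extract", "prune", "select", "fit",
                                       "predict", "calibrate", "assess"),
                            seed = 1L, max_fallback_km = 50,
                            prune_threshold = 0.9, n_trees = 3000,
                            selection = list(), cv = list(k = 10, repeats = 5),
                            calibration = list(), radii_km = c(10, 20, 50),
                            eml = FALSE) {
  sample_schema <- match.arg(sample_schema)
  stages <- match.arg(stages, several.ok = TRUE)
  for (p in c(sample_table, covariate_dir, site_table, new_table))
    if (!is.null(p) && !file.exists(p))
      stop("configured path does not exist: ", p)
  if ("calibrate" %in% stages && is.null(new_table))
    stages <- setdiff(stages, "calibrate")
  if ("assess" %in% stages && is.null(site_table))
    stages <- setdiff(stages, "assess")
  structure(list(
    sample_table = sample_table, covariate_dir = covariate_dir,
    out_dir = out_dir, site_table = site_table, new_table = new_table,
    sample_schema = sample_schema, stages = stages, seed = as.integer(seed),
    max_fallback_km = max_fallback_km, prune_threshold = prune_threshold,
    n_trees = n_trees, selection = selection, cv = cv,
    calibration = calibration, radii_km = radii_km, eml = eml
  ), class = "pipeline_config")
}

read_covariate_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.asc$", full.names = TRUE)
  files <- files[!grepl("^(truth|geology)\\.asc$", basename(files))]
  if (length(files) == 0) stop("no .asc rasters in ", dir)
  nms <- sub("\\.asc$", "", basename(files))
  unknown <- setdiff(nms, covariate_registry()$name)
  if (length(unknown) > 0)
    stop("rasters not in the covariate registry: ",
         paste(unknown, collapse = ", "))
  stack <- lapply(files, read_raster)
  names(stack) <- nms
  stack[intersect(covariate_registry()$name, nms)]
}

#' Run the isoscape pipeline
#'
#' Executes the configured stages in order, writes every intermediate and
#' product under `out_dir`, and returns a manifest of output files with
#' content hashes. Rerunning an identical configuration reproduces the
#' hashes of all seeded stages.
#'
#' @param config A [pipeline_config()], or the path to a YAML file whose
#'   keys are `pipeline_config()` arguments.
#' @return Tibble manifest (file, md5), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    args <- yaml::read_yaml(config)
    config <- do.call(pipeline_config, args)
  }
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[pipeline] ", ...)

  samples <- read_sample_table(cfg$sample_table, cfg$sample_schema)
  stack <- read_covariate_dir(cfg$covariate_dir)

  cm <- NULL; retained <- NULL; sel <- NULL; model <- NULL; product <- NULL
  if ("extract" %in% cfg$stages) {
    log_stage("extract: ", nrow(samples), " sites x ", length(stack),
              " covariates")
    cm <- extract_at_points(stack, samples, cfg$max_fallback_km)
    readr::write_csv(cm$data, file.path(cfg$out_dir, "covariate_matrix.csv"))
  }
  if ("prune" %in% cfg$stages) {
    pr <- prune_correlated(cm, cfg$prune_threshold)
    retained <- pr$retained
    log_stage("prune: ", length(retained), " of ",
              length(cm$covariate_names), " covariates retained (max |R| ",
              signif(pr$max_abs_r, 3), ")")
    jsonlite::write_json(
      list(retained = pr$retained, max_abs_r = pr$max_abs_r,
           dropped = pr$dropped),
      file.path(cfg$out_dir, "pruning_report.json"), auto_unbox = TRUE)
  }
  if ("select" %in% cfg$stages) {
    args <- utils::modifyList(list(matrix = cm, seed = cfg$seed + 1L),
                              cfg$selection)
    if (!is.null(retained)) {
      sub <- cm
      sub$covariate_names <- retained
      args$matrix <- sub
    }
    sel <- do.call(select_variables, args)
    log_stage("select: prediction set {",
              paste(sel$prediction, collapse = ", "), "}")
    jsonlite::write_json(
      list(threshold = sel$threshold, thresholded = sel$thresholded,
           interpretation = sel$interpretation, prediction = sel$prediction),
      file.path(cfg$out_dir, "selection_report.json"), auto_unbox = TRUE)
  }
  selected <- if (!is.null(sel) && sel$informative) sel$prediction
              else retained %||% names(stack)
  if ("fit" %in% cfg$stages) {
    model <- fit_rf(cm, selected, n_trees = cfg$n_trees, seed = cfg$seed + 2L)
    cvm <- cross_validate(cm, selected, k = cfg$cv$k,
                          repeats = cfg$cv$repeats, n_trees = cfg$n_trees,
                          seed = cfg$seed + 3L)
    log_stage(sprintf("fit: CV RMSE %.4g, R2 %.3f", cvm$rmse, cvm$r2))
    jsonlite::write_json(
      list(n_trees = cfg$n_trees, covariates = selected,
           cv_rmse = cvm$rmse, cv_r2 = cvm$r2,
           oob_mse = model$fit$prediction.error),
      file.path(cfg$out_dir, "rf_metrics.json"), auto_unbox = TRUE)
    readr::write_csv(importance_scores(model),
                     file.path(cfg$out_dir, "rf_importance.csv"))
  }
  if ("predict" %in% cfg$stages) {
    product <- predict_raster(model, stack)
    write_isoscape(product, cfg$out_dir, "rf")
    log_stage("predict: rf prediction + sd rasters written")
    if (cfg$eml) {
      sm <- fit_stack(cm, samples, stack_spec(seed = cfg$seed + 4L),
                      selected = selected)
      eml_prod <- predict_raster_stack(sm, stack)
      write_isoscape(eml_prod, cfg$out_dir, "eml")
      log_stage("predict: eml prediction + sd rasters written")
    }
  }
  if ("calibrate" %in% cfg$stages) {
    new_samples <- read_sample_table(cfg$new_table, cfg$sample_schema)
    new_cm <- extract_at_points(stack, new_samples, cfg$max_fallback_km)
    args <- utils::modifyList(
      list(base = cm, new = new_cm, selected = selected,
           seed = cfg$seed + 5L),
      cfg$calibration)
    curve <- do.call(incremental_calibration, args)
    readr::write_csv(curve, file.path(cfg$out_dir, "calibration_curve.csv"))
    readr::write_csv(summarize_calibration(curve),
                     file.path(cfg$out_dir, "calibration_summary.csv"))
    log_stage("calibrate: ", nrow(curve), " (fraction, repeat) cells")
  }
  if ("assess" %in% cfg$stages) {
    st <- read_sample_table(cfg$site_table, "sm2")
    assessment <- assess_sites(product, st, cfg$radii_km)
    readr::write_csv(assessment, file.path(cfg$out_dir, "site_assessment.csv"))
    readr::write_csv(attr(assessment, "ranges"),
                     file.path(cfg$out_dir, "site_ranges.csv"))
    log_stage("assess: ", nrow(assessment), " site groups")
  }

  files <- setdiff(list.files(cfg$out_dir, full.names = TRUE,
                              recursive = TRUE),
                   file.path(cfg$out_dir, "manifest.json"))
  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"))
  invisible(manifest)
}
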