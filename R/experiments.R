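# Self-contained simulation experiments over the synthetic landscape.
# These are the computations behind the numbered analysis scripts and the
# acceptance checks: each one builds its own inputs from a seed, runs the
# pipeline stage under study, and returns the measured quantities.

#' Truth-recovery experiment
#'
#' Generates a default synthetic world, extracts and prunes covariates,
#' fits the forest isoscape and predicts it over the full grid, then
#' scores the prediction against the known true surface.
#'
#' @param seed Integer seed for the world and the fits.
#' @param config Optional [sim_config()] override (the seed argument still
#'   wins).
#' @param n_trees Trees in the final forest.
#' @return List: `r2` (raster-wide R-squared against truth), `rmse_raster`,
#'   `world`, `matrix`, `retained`, `model`, `product`.
#' @export
experiment_truth_recovery <- function(seed = 1L, config = NULL,
                                      n_trees = 3000) {
  cfg <- config %||% sim_config(seed = seed)
  cfg$seed <- as.integer(seed)
  w <- generate_world(cfg)
  cm <- extract_at_points(w$covariates, w$samples)
  pr <- prune_correlated(cm)
  m <- fit_rf(cm, pr$retained, n_trees = n_trees, seed = seed + 1L)
  prod <- predict_raster(m, w$covariates)
  pred <- rg_values(prod$prediction)
  truth <- rg_values(w$truth)
  r2 <- 1 - sum((pred - truth)^2) / sum((truth - mean(truth))^2)
  list(r2 = r2, rmse_raster = sqrt(mean((pred - truth)^2)),
       world = w, matrix = cm, retained = pr$retained, model = m,
       product = prod)
}

#' Quantile-forest interval-coverage experiment
#'
#' Draws an independent uniformly located test campaign over the same
#' world, predicts with the trained quantile forest, and measures the
#' share of test measurements inside `[pred - sd, pred + sd]`, whose
#' nominal level is the 68.27% central interval.
#'
#' @param rec Output of [experiment_truth_recovery()].
#' @param n_test Number of iid test sites.
#' @param seed Integer seed for the test draw.
#' @return List: `coverage_pct`, `mean_sd`, `n_test`.
#' @export
experiment_qrf_coverage <- function(rec, n_test = 1000, seed = 2L) {
  w <- rec$world
  test <- sample_sites(w, n_test, clustering_fraction = 0, seed = seed)
  tm <- extract_at_points(w$covariates, test)
  x <- cm_predictors(tm, rec$model$covariates)
  pred <- predict(rec$model, x)
  q <- predict(rec$model, x, type = "quantiles")
  sdv <- (q[, 2] - q[, 1]) / 2
  inside <- test$sr_ratio >= pred - sdv & test$sr_ratio <= pred + sdv
  list(coverage_pct = 100 * mean(inside), mean_sd = mean(sdv),
       n_test = n_test)
}

#' Exhaustive-scan oracle checks for buffer ranges and fallback extraction
#'
#' On a random grid with nodata holes, compares [local_range()] and the
#' nearest-valid-cell fallback of [extract_at_points()] against brute-force
#' scans over every cell centre.
#'
#' @param seed Integer seed.
#' @param n_grid Grid side length (cells).
#' @param n_checks Number of random sites/radii probed.
#' @return List: `range_mismatches`, `fallback_mismatches` (both 0 when
#'   the implementations agree exactly), `n_checks`.
#' @export
experiment_oracle_equivalence <- function(seed = 3L, n_grid = 60,
                                          n_checks = 20) {
  with_seed(seed, {
    m <- matrix(stats::runif(n_grid^2, 0.705, 0.720), n_grid, n_grid)
    m[sample(n_grid^2, round(n_grid^2 * 0.05))] <- NA
    g <- raster_grid(m, xmin = 100, ymax = 48, dx = 1 / 110.574)
    ctr <- rg_cell_centers(g)
    v <- rg_values(g)
    valid <- which(!is.na(v), arr.ind = TRUE)
    dv <- function(lon, lat) gc_distance_km(ctr$x[valid[, 2]],
                                            ctr$y[valid[, 1]], lon, lat)
    range_bad <- 0L; fb_bad <- 0L
    for (i in seq_len(n_checks)) {
      lon <- stats::runif(1, min(ctr$x) + 0.05, max(ctr$x) - 0.05)
      lat <- stats::runif(1, min(ctr$y) + 0.05, max(ctr$y) - 0.05)
      r <- stats::runif(1, 2, 15)
      got <- local_range(g, lon, lat, r)
      inside <- dv(lon, lat) <= r
      vals <- v[valid[inside, , drop = FALSE]]
      if (!identical(unname(got), c(min(vals), max(vals))))
        range_bad <- range_bad + 1L
    }
    holes <- which(is.na(v), arr.ind = TRUE)
    probe <- holes[sample(nrow(holes), min(n_checks, nrow(holes))), ,
                   drop = FALSE]
    for (i in seq_len(nrow(probe))) {
      lon <- ctr$x[probe[i, 2]]; lat <- ctr$y[probe[i, 1]]
      cm <- extract_at_points(list(cov = g),
                              tibble::tibble(id = "p", longitude = lon,
                                             latitude = lat),
                              max_fallback_km = 1e4)
      d <- dv(lon, lat)
      best <- valid[which.min(d), ]
      if (cm$data$cov != v[best[1], best[2]]) fb_bad <- fb_bad + 1L
    }
    list(range_mismatches = range_bad, fallback_mismatches = fb_bad,
         n_checks = n_checks)
  })
}

#' Correlation-pruning contract over random matrices
#'
#' Generates random predictor matrices seeded with strongly correlated
#' pairs and duplicated columns, prunes each at |R| = 0.9, and returns the
#' worst post-pruning pairwise correlation observed.
#'
#' @param seed Integer seed.
#' @param n_matrices Number of random matrices.
#' @return List: `max_abs_r` (maximum over all matrices), `n_matrices`.
#' @export
experiment_pruning_contract <- function(seed = 4L, n_matrices = 100) {
  with_seed(seed, {
    worst <- 0
    for (i in seq_len(n_matrices)) {
      n <- 80
      base <- matrix(stats::rnorm(n * 6), n, 6)
      rho <- stats::runif(2, 0.85, 0.999)
      x <- cbind(base,
                 rho[1] * base[, 1] + sqrt(1 - rho[1]^2) * stats::rnorm(n),
                 rho[2] * base[, 2] + sqrt(1 - rho[2]^2) * stats::rnorm(n),
                 base[, 3])
      colnames(x) <- paste0("v", seq_len(ncol(x)))
      pr <- prune_correlated(as_response_matrix(x, stats::rnorm(n)),
                             threshold = 0.9)
      worst <- max(worst, pr$max_abs_r)
    }
    list(max_abs_r = worst, n_matrices = n_matrices)
  })
}

#' Variable-selection recovery experiment
#'
#' Repeats the three-step selection on a task with 3 informative and
#' `p_noise` pure-noise predictors and counts the seeds in which all
#' informative predictors are kept and at least 90% of the noise is
#' discarded.
#'
#' @param seed Master seed (per-repeat seeds derive from it).
#' @param n_seeds Number of repeats.
#' @param n Observations per task.
#' @param p_noise Pure-noise predictors per task.
#' @param ... Passed to [select_variables()].
#' @return List: `successes`, `n_seeds`, per-seed detail tibble.
#' @export
experiment_selection_recovery <- function(seed = 5L, n_seeds = 10, n = 400,
                                          p_noise = 20, ...) {
  detail <- purrr::map_dfr(seq_len(n_seeds), function(i) {
    task <- selection_task_data(n = n, p_noise = p_noise, seed = seed + i)
    sel <- select_variables(task, seed = seed + 100L + i, ...)
    kept <- sel$prediction
    tibble::tibble(
      seed = seed + i,
      informative_kept = sum(c("inf1", "inf2", "inf3") %in% kept),
      noise_kept = sum(grepl("^noise", kept)),
      success = all(c("inf1", "inf2", "inf3") %in% kept) &
        sum(grepl("^noise", kept)) <= ceiling(0.1 * p_noise))
  })
  list(successes = sum(detail$success), n_seeds = n_seeds, detail = detail)
}

# regression task with a known informative set (3 signal + noise columns)
selection_task_data <- function(n = 400, p_noise = 20, seed = 1L) {
  with_seed(seed, {
    p <- 3 + p_noise
    x <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, c(paste0("inf", 1:3),
                                        paste0("noise", seq_len(p_noise)))))
    y <- x[, 1] + 0.8 * x[, 2] + 0.6 * x[, 3] + stats::rnorm(n, 0, 0.5)
    as_response_matrix(x, y)
  })
}

#' Attach a response to a plain predictor matrix
#'
#' Lightweight alternative to a full covariate matrix for simulation
#' tasks: the response rides along as an attribute understood by the
#' fitting functions.
#'
#' @param x Numeric predictor matrix (named columns).
#' @param y Response vector.
#' @return `x` with attribute `response`.
#' @export
as_response_matrix <- function(x, y) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  stopifnot(nrow(x) == length(y))
  attr(x, "response") <- y
  x
}

#' Under-sampled-province calibration experiment
#'
#' Splits a default world's campaign into base sites (outside the dense
#' cluster disc) and a new regional set (the clustered sites), runs the
#' incremental calibration over 0-100% in 10% steps with 10 repeats, and
#' summarises the accuracy/precision trajectory.
#'
#' @param seed Integer seed.
#' @param rec Optional [experiment_truth_recovery()] output to reuse its
#'   world and covariate matrix.
#' @param n_trees Trees per calibration forest.
#' @param repeats Random draws per fraction.
#' @return List: `curve`, `summary`, `spearman_rho` (mean held-out RMSE vs
#'   fraction, computed over fractions < 1), `rmse_f0`, `rmse_f10`,
#'   `rmse_f100`, `sd_f0`, `sd_f10`, `sd_f100`.
#' @export
experiment_calibration <- function(seed = 6L, rec = NULL, n_trees = 500,
                                   repeats = 10) {
  rec <- rec %||% experiment_truth_recovery(seed)
  w <- rec$world; cm <- rec$matrix
  s <- w$samples
  ctr <- attr(s, "cluster_center")
  d <- gc_distance_km(s$longitude, s$latitude, ctr["lon"], ctr["lat"])
  new_idx <- which(s$clustered)
  base_idx <- which(!s$clustered & d > ctr["radius_km"])
  pick <- function(idx) { m <- cm; m$data <- cm$data[idx, ]; m }
  curve <- incremental_calibration(pick(base_idx), pick(new_idx),
                                   selected = rec$retained,
                                   repeats = repeats, n_trees = n_trees,
                                   seed = seed + 1L)
  sm <- summarize_calibration(curve)
  held_out <- sm[sm$fraction < 1, ]
  rho <- stats::cor(held_out$fraction, held_out$mean_rmse,
                    method = "spearman")
  at <- function(col, f) sm[[col]][abs(sm$fraction - f) < 1e-9]
  list(curve = curve, summary = sm, spearman_rho = rho,
       rmse_f0 = at("mean_rmse", 0), rmse_f10 = at("mean_rmse", 0.1),
       rmse_f100 = at("mean_rmse", 1),
       sd_f0 = at("mean_sd", 0), sd_f10 = at("mean_sd", 0.1),
       sd_f100 = at("mean_sd", 1))
}

#' Super-learner dominance experiment
#'
#' Across independently seeded synthetic worlds, fits the stacked
#' ensemble and counts how often its spatially blocked CV RMSE is within
#' `margin` of the best base learner (the stacking guarantee is
#' asymptotic; the margin absorbs finite-sample noise).
#'
#' @param seed Master seed.
#' @param n_seeds Number of worlds.
#' @param margin Allowed excess over the best base learner, ratio units.
#' @param n_sites Sites per world.
#' @return List: `wins`, `n_seeds`, detail tibble with stack/best-base
#'   RMSE per seed.
#' @export
experiment_stacking_dominance <- function(seed = 7L, n_seeds = 10,
                                          margin = 0.0005, n_sites = 250) {
  sel <- c("r.srsrq1", "r.age", "r.minage_geol", "r.maxage_geol",
           "r.mat", "r.map")
  detail <- purrr::map_dfr(seq_len(n_seeds), function(i) {
    cfg <- sim_config(grid_width = 60, grid_height = 60, n_sites = n_sites,
                      seed = seed + i)
    w <- generate_world(cfg)
    cm <- extract_at_points(w$covariates[sel], w$samples)
    sm <- suppressMessages(
      fit_stack(cm, w$samples, stack_spec(seed = seed + 50L + i),
                selected = sel))
    tibble::tibble(seed = seed + i,
                   stack_rmse = unname(sm$cv$stack["rmse"]),
                   best_base_rmse = min(sm$cv$base[, "rmse"]))
  })
  list(wins = sum(detail$stack_rmse <= detail$best_base_rmse + margin),
       n_seeds = n_seeds, detail = detail)
}

#' RF vs stacked-ensemble agreement experiment
#'
#' Fits both isoscapes on the same synthetic world and compares the
#' prediction surfaces and the upper tail of the uncertainty surfaces.
#'
#' @param seed Integer seed.
#' @param n_sites Sites in the campaign.
#' @return List: `mean_abs_diff` (RF vs EML prediction), `rf_sd_q99`,
#'   `eml_sd_q99`.
#' @export
experiment_rf_eml_agreement <- function(seed = 8L, n_sites = 250) {
  sel <- c("r.srsrq1", "r.age", "r.minage_geol", "r.maxage_geol",
           "r.mat", "r.map")
  cfg <- sim_config(grid_width = 60, grid_height = 60, n_sites = n_sites,
                    seed = seed)
  w <- generate_world(cfg)
  cm <- extract_at_points(w$covariates[sel], w$samples)
  m_rf <- fit_rf(cm, sel, n_trees = 1000, seed = seed + 1L)
  rf_prod <- predict_raster(m_rf, w$covariates)
  sm <- suppressMessages(
    fit_stack(cm, w$samples, stack_spec(seed = seed + 2L), selected = sel))
  eml_prod <- predict_raster_stack(sm, w$covariates)
  dif <- abs(rg_values(eml_prod$prediction) - rg_values(rf_prod$prediction))
  list(mean_abs_diff = mean(dif),
       rf_sd_q99 = unname(stats::quantile(rg_values(rf_prod$sd), 0.99)),
       eml_sd_q99 = unname(stats::quantile(rg_values(eml_prod$sd), 0.99)))
}

#' Site-assessment monotonicity experiment
#'
#' Builds an archaeological-style site fixture over a synthetic isoscape
#' product and checks that every site's within-range proportion is
#' non-decreasing across the 10/20/50 km radii.
#'
#' @param rec Output of [experiment_truth_recovery()].
#' @param n_sites Number of fixture sites.
#' @param seed Integer seed.
#' @return List: `fraction_monotone` (1 when the structural invariant
#'   holds everywhere), `assessment` tibble.
#' @export
experiment_table2_invariant <- function(rec, n_sites = 8, seed = 9L) {
  w <- rec$world
  ctr <- rg_cell_centers(w$truth)
  nr <- nrow(w$truth$values); nc <- ncol(w$truth$values)
  df <- with_seed(seed, {
    rows <- sample(5:(nr - 5), n_sites); cols <- sample(5:(nc - 5), n_sites)
    purrr::map_dfr(seq_len(n_sites), function(i) tibble::tibble(
      site = sprintf("fix%02d", i),
      longitude = ctr$x[cols[i]], latitude = ctr$y[rows[i]],
      material = sample(c("human", "animal", "plant"), 1),
      period = sample(c("LBA", "Xiongnu", "modern"), 1),
      sr_ratio = w$truth$values[rows[i], cols[i]] +
        stats::rnorm(5, 0, 0.0015),
      source = "syn", coord_provenance = "exact"))
  })
  assessment <- assess_sites(rec$product, site_table(df),
                             radii_km = c(10, 20, 50))
  props <- as.matrix(assessment[paste0("prop_", c(10, 20, 50), "km")])
  mono <- apply(props, 1, function(p) all(diff(p) >= 0))
  list(fraction_monotone = mean(mono), assessment = assessment)
}
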