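# Stacked-ensemble (super-learner) isoscape. Five base learners are trained
# on spatially blocked folds; a linear meta-learner is fit on their
# out-of-fold predictions only, so it never sees in-fold leakage. Oblique
# geographic coordinates (rotated planar axes) enter as covariates to carry
# broad-scale spatial trend; spatial blocking by k-means keeps the CV
# honest under clustered sampling.

#' Oblique geographic coordinate features
#'
#' For each angle theta, the feature is `x cos(theta) + y sin(theta)` on
#' planar kilometre coordinates: the points' positions along a rotated
#' axis.
#'
#' @param xy Two-column matrix of planar coordinates (km), e.g. from
#'   [project_local_km()].
#' @param angles_deg Angles in degrees, each in \[0, 180).
#' @return Matrix with one `oblique_<angle>` column per angle (zero
#'   columns, with a warning, when `angles_deg` is empty).
#' @export
oblique_coordinates <- function(xy, angles_deg = c(0, 45, 90, 135)) {
  if (length(angles_deg) == 0) {
    warning("empty angle set: no oblique coordinate features generated")
    return(matrix(numeric(0), nrow = nrow(xy), ncol = 0))
  }
  if (any(angles_deg < 0 | angles_deg >= 180))
    stop("oblique angles must lie in [0, 180)")
  th <- angles_deg * pi / 180
  out <- sapply(th, function(a) xy[, 1] * cos(a) + xy[, 2] * sin(a))
  out <- matrix(out, nrow = nrow(xy))
  colnames(out) <- sprintf("oblique_%03d", round(angles_deg))
  out
}

#' Specification of the stacked ensemble
#'
#' @param learners Base learners, a subset of
#'   `c("rf", "gbm", "svm", "nnet", "glmnet")` (forest, gradient boosting,
#'   support-vector regression, feed-forward neural network, elastic-net
#'   linear model). At least two.
#' @param k_folds Spatial CV folds (default 5).
#' @param angles_deg Oblique-coordinate angles.
#' @param rf_trees Trees for the forest base learner and the uncertainty
#'   quantile forest.
#' @param seed Integer seed.
#' @return A `stack_spec` list.
#' @export
stack_spec <- function(learners = c("rf", "gbm", "svm", "nnet", "glmnet"),
                       k_folds = 5, angles_deg = c(0, 45, 90, 135),
                       rf_trees = 500, seed = 1L) {
  learners <- match.arg(learners, several.ok = TRUE)
  if (length(learners) < 2) stop("need at least 2 base learners")
  structure(list(learners = learners, k_folds = k_folds,
                 angles_deg = angles_deg, rf_trees = rf_trees,
                 seed = as.integer(seed)),
            class = "stack_spec")
}

# --- base-learner interface ------------------------------------------------
# Each learner must train on an (x, y) pair and predict on new x. Failures
# (non-convergence, degenerate input) are caught by the caller and the
# learner is excluded from the stack with a diagnostic.

fit_base <- function(name, x, y, spec, seed) {
  switch(name,
    rf = fit_forest(x, y, num_trees = spec$rf_trees, seed = seed),
    gbm = {
      dm <- xgboost::xgb.DMatrix(x, label = y)
      xgboost::xgb.train(
        params = list(objective = "reg:squarederror", max_depth = 6,
                      eta = 0.3, nthread = 1, seed = seed),
        data = dm, nrounds = 100, verbose = 0)
    },
    svm = e1071::svm(x, y, kernel = "radial"),
    nnet = {
      mx <- colMeans(x); sx <- apply(x, 2, stats::sd); sx[sx == 0] <- 1
      my <- mean(y); sy <- stats::sd(y); if (sy == 0) sy <- 1
      xs <- scale(x, mx, sx)
      net <- with_seed(seed,
        nnet::nnet(xs, (y - my) / sy, size = 5, decay = 0.01,
                   linout = TRUE, maxit = 500, trace = FALSE))
      list(net = net, mx = mx, sx = sx, my = my, sy = sy)
    },
    glmnet = with_seed(seed,
      glmnet::cv.glmnet(x, y, alpha = 0.5, nfolds = 5)),
    stop("unknown base learner: ", name)
  )
}

predict_base <- function(name, model, x) {
  switch(name,
    rf = stats::predict(model, data = as.data.frame(x),
                        num.threads = 1)$predictions,
    gbm = stats::predict(model, xgboost::xgb.DMatrix(x)),
    svm = as.numeric(stats::predict(model, x)),
    nnet = as.numeric(stats::predict(model$net, scale(x, model$mx, model$sx))) *
      model$sy + model$my,
    glmnet = as.numeric(stats::predict(model, x, s = "lambda.min"))
  )
}

#' Fit the stacked-ensemble isoscape
#'
#' @param matrix A `covariate_matrix` or numeric predictor matrix with
#'   attribute `response`.
#' @param coords Tibble/data frame with `longitude`, `latitude` for every
#'   row of `matrix` (used for oblique features and spatial blocking).
#' @param spec A [stack_spec()].
#' @param selected Optional covariate subset.
#' @return A `stack_model` with the refit base learners, the linear
#'   meta-learner, spatially blocked CV metrics for the stack and each
#'   base learner, the uncertainty quantile forest, and the fold
#'   assignment.
#' @export
fit_stack <- function(matrix, coords, spec = stack_spec(), selected = NULL) {
  x0 <- cm_predictors(matrix, selected)
  y <- cm_response(matrix)
  stopifnot(!is.null(y), nrow(x0) == length(y),
            nrow(coords) == length(y))
  center <- c(mean(coords$longitude), mean(coords$latitude))
  xy <- project_local_km(coords$longitude, coords$latitude, center)
  obl <- oblique_coordinates(xy, spec$angles_deg)
  x <- cbind(x0, obl)

  with_seed(spec$seed, {
    km <- stats::kmeans(xy, centers = min(spec$k_folds, nrow(xy)),
                        nstart = 10)
    folds <- km$cluster
    # one seed per learner, assigned by sorted name so the stack is
    # invariant under permutation of the learner list
    sorted <- sort(spec$learners)
    seeds <- sample.int(.Machine$integer.max, length(sorted))
    names(seeds) <- sorted

    # out-of-fold base predictions (never in-fold)
    oof <- matrix(NA_real_, nrow(x), length(spec$learners),
                  dimnames = list(NULL, spec$learners))
    failed <- character()
    for (ln in spec$learners) {
      ok <- TRUE
      for (f in sort(unique(folds))) {
        tr <- folds != f
        res <- tryCatch({
          m <- fit_base(ln, x[tr, , drop = FALSE], y[tr], spec, seeds[ln])
          predict_base(ln, m, x[!tr, , drop = FALSE])
        }, error = function(e) e)
        if (inherits(res, "error")) {
          message("base learner '", ln, "' failed (", conditionMessage(res),
                  "); excluded from the stack")
          failed <- c(failed, ln); ok <- FALSE; break
        }
        oof[!tr, ln] <- res
      }
      if (!ok) oof[, ln] <- NA_real_
    }
    active <- setdiff(spec$learners, failed)
    if (length(active) == 0) stop("every base learner failed")

    meta_df <- as.data.frame(oof[, active, drop = FALSE])
    meta_df$..y.. <- y
    meta <- stats::lm(..y.. ~ ., data = meta_df)

    # honest stack CV: refit the meta-combination without each fold
    stack_cv_pred <- numeric(length(y))
    for (f in sort(unique(folds))) {
      tr <- folds != f
      mf <- stats::lm(..y.. ~ ., data = meta_df[tr, , drop = FALSE])
      stack_cv_pred[!tr] <- stats::predict(mf, meta_df[!tr, , drop = FALSE])
    }
    metric <- function(p) c(rmse = sqrt(mean((p - y)^2)),
                            r2 = 1 - sum((p - y)^2) / sum((y - mean(y))^2))
    base_cv <- t(vapply(active, function(ln) metric(oof[, ln]), numeric(2)))
    stack_cv <- metric(stack_cv_pred)

    full <- lapply(active, function(ln)
      fit_base(ln, x, y, spec, seeds[ln]))
    names(full) <- active

    qrf <- fit_forest(x, y, num_trees = spec$rf_trees,
                      seed = sample.int(.Machine$integer.max, 1),
                      quantreg = TRUE)

    structure(list(
      spec = spec, covariates = colnames(x0), center = center,
      learners = active, failed = failed, base_models = full,
      meta = meta, qrf = qrf, folds = folds,
      cv = list(stack = stack_cv, base = base_cv),
      response_range = range(y)
    ), class = "stack_model")
  })
}

#' @export
print.stack_model <- function(x, ...) {
  cat(sprintf("<stack_model> %d base learners (%s), stack CV RMSE %.4g, R2 %.3f\n",
              length(x$learners), paste(x$learners, collapse = ", "),
              x$cv$stack["rmse"], x$cv$stack["r2"]))
  invisible(x)
}

# Meta-combined prediction on a plain feature matrix (covariates + oblique)
predict_stack_rows <- function(model, x) {
  base <- sapply(model$learners, function(ln)
    predict_base(ln, model$base_models[[ln]], x))
  base <- matrix(base, nrow = nrow(x),
                 dimnames = list(NULL, model$learners))
  as.numeric(stats::predict(model$meta, as.data.frame(base)))
}

#' Predict at sample rows with the stacked ensemble
#'
#' @param object A `stack_model`.
#' @param newdata Covariate rows (model covariates as columns).
#' @param coords `longitude`/`latitude` for each row.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.stack_model <- function(object, newdata, coords, ...) {
  x0 <- as.matrix(as.data.frame(newdata)[object$covariates])
  xy <- project_local_km(coords$longitude, coords$latitude, object$center)
  x <- cbind(x0, oblique_coordinates(xy, object$spec$angles_deg))
  predict_stack_rows(object, x)
}

#' Predict the stacked-ensemble isoscape over a raster stack
#'
#' Prediction is the meta-combination of the base learners; the SD surface
#' comes from a quantile forest fit to the same training data (including
#' oblique features), using the same 68.27% interval convention as the RF
#' product.
#'
#' @param model A `stack_model`.
#' @param stack Named list of aligned `raster_grid`s covering the model
#'   covariates.
#' @param quantile_pair Quantile levels bounding the interval.
#' @return An `isoscape_product` with `metadata$model = "eml"`.
#' @export
predict_raster_stack <- function(model, stack,
                                 quantile_pair = c(0.158655, 0.841345)) {
  miss <- setdiff(model$covariates, names(stack))
  if (length(miss) > 0)
    stop("stack lacks model covariate(s): ", paste(miss, collapse = ", "))
  ref <- stack[[model$covariates[1]]]
  for (nm in model$covariates)
    if (!rg_aligned(ref, stack[[nm]]))
      stop("raster '", nm, "' is not aligned with the stack")
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  ctr <- rg_cell_centers(ref)
  lon <- rep(ctr$x, each = nr); lat <- rep(ctr$y, times = nc)

  cols <- lapply(model$covariates, function(nm) as.vector(rg_values(stack[[nm]])))
  x0 <- do.call(cbind, cols)
  colnames(x0) <- model$covariates
  ok <- stats::complete.cases(x0)

  pred <- rep(NA_real_, nr * nc); sdv <- rep(NA_real_, nr * nc)
  if (any(ok)) {
    xy <- project_local_km(lon[ok], lat[ok], model$center)
    x <- cbind(x0[ok, , drop = FALSE],
               oblique_coordinates(xy, model$spec$angles_deg))
    pred[ok] <- predict_stack_rows(model, x)
    q <- stats::predict(model$qrf, data = as.data.frame(x),
                        type = "quantiles", quantiles = quantile_pair,
                        num.threads = 1)$predictions
    sdv[ok] <- (q[, 2] - q[, 1]) / 2
  }
  mk <- function(v) raster_grid(matrix(v, nr, nc), xmin = ref$xmin,
                                ymax = ref$ymax, dx = ref$dx, dy = ref$dy,
                                crs = ref$crs, nodata = ref$nodata)
  structure(list(
    prediction = mk(pred), sd = mk(sdv),
    metadata = list(model = "eml", learners = model$learners,
                    angles_deg = model$spec$angles_deg,
                    quantile_pair = quantile_pair,
                    response_range = model$response_range)
  ), class = "isoscape_product")
}
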