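# Random-forest isoscape: a bagged regression-tree ensemble on the selected
# covariates, evaluated by repeated k-fold CV, with node-impurity variable
# importance, partial dependence, and a quantile-forest uncertainty surface.
# The same forest serves both the mean prediction and the conditional
# quantiles (its leaves retain the response distribution), so the SD map
# costs no second fit.

#' Fit the random-forest isoscape model
#'
#' @param matrix A `covariate_matrix`, or numeric predictor matrix with
#'   attribute `response`.
#' @param selected Covariate names to use (must be columns of `matrix`).
#' @param n_trees Number of trees (default 3000).
#' @param mtry Per-split candidate count; defaults to `floor(p/3)`,
#'   minimum 1.
#' @param min_node Minimum terminal-node size; defaults to 20 because the
#'   forest doubles as a quantile forest and small leaves undercover.
#' @param seed Integer seed.
#' @return An `isoscape_model`: the trained ensemble plus training data,
#'   per-covariate training ranges, OOB predictions and impurity
#'   importance.
#' @export
fit_rf <- function(matrix, selected = NULL, n_trees = 3000, mtry = NULL,
                   min_node = NULL, seed = 1L) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  x <- cm_predictors(matrix, selected)
  y <- cm_response(matrix)
  stopifnot(!is.null(y), nrow(x) == length(y))
  fit <- fit_forest(x, y, num_trees = n_trees, seed = seed,
                    importance = "impurity", quantreg = TRUE, mtry = mtry,
                    min_node = min_node)
  structure(list(
    fit = fit, x = x, y = y, covariates = colnames(x),
    n_trees = n_trees, seed = as.integer(seed),
    training_range = apply(x, 2, range),
    response_range = range(y),
    oob_predictions = fit$predictions
  ), class = "isoscape_model")
}

#' @export
print.isoscape_model <- function(x, ...) {
  cat(sprintf("<isoscape_model> %d trees, %d covariates, n = %d, OOB MSE %.3g\n",
              x$n_trees, length(x$covariates), length(x$y),
              x$fit$prediction.error))
  invisible(x)
}

#' Predict at new covariate rows
#'
#' @param object An `isoscape_model`.
#' @param newdata Matrix/data frame with the model's covariate columns.
#' @param type `"response"` (forest mean) or `"quantiles"`.
#' @param quantiles Quantile levels for `type = "quantiles"`.
#' @param ... Unused.
#' @return Numeric vector, or matrix of quantiles.
#' @export
predict.isoscape_model <- function(object, newdata,
                                   type = c("response", "quantiles"),
                                   quantiles = c(0.158655, 0.841345), ...) {
  type <- match.arg(type)
  nd <- as.data.frame(newdata)[object$covariates]
  if (type == "response")
    stats::predict(object$fit, data = nd, num.threads = 1)$predictions
  else
    stats::predict(object$fit, data = nd, type = "quantiles",
                   quantiles = quantiles, num.threads = 1)$predictions
}

#' Repeated k-fold cross-validation of the forest isoscape
#'
#' Fold assignment is re-randomised per repeat under the seed. RMSE is
#' pooled over held-out predictions; R-squared is `1 - SSE/SST` on held-out
#' predictions (and can be negative).
#'
#' @inheritParams fit_rf
#' @param k Folds (default 10).
#' @param repeats Repeats (default 5).
#' @return List with pooled `rmse`, `r2`, and `per_repeat` tibble.
#' @export
cross_validate <- function(matrix, selected = NULL, k = 10, repeats = 5,
                           n_trees = 3000, seed = 1L) {
  x <- cm_predictors(matrix, selected)
  y <- cm_response(matrix)
  n <- length(y)
  if (k > n) stop("k (", k, ") exceeds the number of observations (", n, ")")
  with_seed(seed, {
    per <- purrr::map_dfr(seq_len(repeats), function(r) {
      fold <- sample(rep_len(seq_len(k), n))
      pred <- numeric(n)
      for (f in seq_len(k)) {
        tr <- fold != f
        m <- fit_forest(x[tr, , drop = FALSE], y[tr], num_trees = n_trees,
                        seed = sample.int(.Machine$integer.max, 1))
        pred[!tr] <- stats::predict(m, data = as.data.frame(x[!tr, , drop = FALSE]),
                                    num.threads = 1)$predictions
      }
      tibble::tibble(repeat_id = r,
                     rmse = sqrt(mean((pred - y)^2)),
                     r2 = 1 - sum((pred - y)^2) / sum((y - mean(y))^2))
    })
    list(rmse = mean(per$rmse), r2 = mean(per$r2), per_repeat = per)
  })
}

#' Node-impurity variable importance
#'
#' @param model An `isoscape_model`.
#' @return Tibble of variables and importance normalised to sum to 1,
#'   sorted decreasing.
#' @export
importance_scores <- function(model) {
  imp <- model$fit$variable.importance
  tot <- sum(imp)
  if (tot == 0) tot <- 1  # constant response: no impurity reduced anywhere
  tibble::tibble(variable = names(imp),
                 importance = as.numeric(imp) / tot) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Partial dependence of the prediction on one covariate
#'
#' At each grid value v, the covariate is set to v for every training row
#' and predictions are averaged.
#'
#' @param model An `isoscape_model`.
#' @param covariate Covariate name.
#' @param grid_points Number of sweep points over the training range, or a
#'   numeric vector of explicit values.
#' @return Tibble with `value` and `yhat`.
#' @export
partial_dependence <- function(model, covariate, grid_points = 25) {
  if (!covariate %in% model$covariates)
    stop("covariate '", covariate, "' is not in the model")
  rng <- model$training_range[, covariate]
  grid <- if (length(grid_points) > 1) grid_points
  else if (rng[1] == rng[2]) rng[1]
  else seq(rng[1], rng[2], length.out = grid_points)
  yhat <- vapply(grid, function(v) {
    xx <- model$x
    xx[, covariate] <- v
    mean(predict(model, xx))
  }, numeric(1))
  tibble::tibble(value = grid, yhat = yhat)
}

#' Predict the isoscape and its uncertainty over a raster stack
#'
#' Per cell, the prediction is the forest mean and the SD is half the
#' 68.27% conditional prediction interval from the quantile forest
#' (`(q_0.8413 - q_0.1587) / 2`). Any cell missing any covariate is nodata
#' in both outputs.
#'
#' @param model An `isoscape_model` (fit with quantile support, the
#'   default).
#' @param stack Named list of `raster_grid`s covering all model covariates,
#'   mutually aligned.
#' @param quantile_pair The two quantile levels bounding the interval.
#' @return An `isoscape_product`: list with `prediction` and `sd` rasters
#'   plus `metadata`.
#' @export
predict_raster <- function(model, stack,
                           quantile_pair = c(0.158655, 0.841345)) {
  miss <- setdiff(model$covariates, names(stack))
  if (length(miss) > 0)
    stop("stack lacks model covariate(s): ", paste(miss, collapse = ", "))
  ref <- stack[[model$covariates[1]]]
  for (nm in model$covariates)
    if (!rg_aligned(ref, stack[[nm]]))
      stop("raster '", nm, "' is not aligned with the stack")

  nr <- nrow(ref$values); nc <- ncol(ref$values)
  cols <- lapply(model$covariates, function(nm) as.vector(rg_values(stack[[nm]])))
  nd <- do.call(cbind, cols)
  colnames(nd) <- model$covariates
  ok <- stats::complete.cases(nd)

  pred <- rep(NA_real_, nr * nc)
  sdv <- rep(NA_real_, nr * nc)
  if (any(ok)) {
    pred[ok] <- predict(model, nd[ok, , drop = FALSE])
    q <- predict(model, nd[ok, , drop = FALSE], type = "quantiles",
                 quantiles = quantile_pair)
    sdv[ok] <- (q[, 2] - q[, 1]) / 2
  }
  mk <- function(v) raster_grid(matrix(v, nr, nc), xmin = ref$xmin,
                                ymax = ref$ymax, dx = ref$dx, dy = ref$dy,
                                crs = ref$crs, nodata = ref$nodata)
  structure(list(
    prediction = mk(pred), sd = mk(sdv),
    metadata = list(model = "rf", n_trees = model$n_trees,
                    covariates = model$covariates,
                    quantile_pair = quantile_pair,
                    response_range = model$response_range,
                    seed = model$seed)
  ), class = "isoscape_product")
}

#' @export
print.isoscape_product <- function(x, ...) {
  v <- rg_values(x$prediction)
  cat(sprintf("<isoscape_product> (%s) %d x %d cells, prediction [%.4f, %.4f]\n",
              x$metadata$model, nrow(x$prediction$values),
              ncol(x$prediction$values),
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' Write an isoscape product to a raster file pair
#'
#' @param product An `isoscape_product`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_isoscape <- function(product, dir, prefix = "isoscape") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, paste0(prefix, "_prediction.asc"))
  p2 <- file.path(dir, paste0(prefix, "_sd.asc"))
  write_raster(product$prediction, p1)
  write_raster(product$sd, p2)
  jsonlite::write_json(product$metadata,
                       file.path(dir, paste0(prefix, "_metadata.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(prediction = p1, sd = p2))
}
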