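# Three-step forest-based variable selection: (1) threshold irrelevant
# predictors on permutation importance, (2) pick the smallest nested model
# within one SD of the minimum OOB error (interpretation set), (3) admit
# variables sequentially only when they beat the OOB noise fluctuation
# (prediction set). The three sets are nested by construction.

# One regression forest; num.threads = 1 keeps results reproducible and
# matches the single-CPU execution model. Quantile-capable forests grow
# larger terminal nodes (20 vs the regression default 5): leaf response
# distributions estimated from a handful of in-bag values are too narrow
# and undercover, while ~20 values per leaf give calibrated conditional
# quantiles at negligible cost to the mean prediction.
fit_forest <- function(x, y, num_trees = 300, seed = 1,
                       importance = "none", quantreg = FALSE,
                       mtry = NULL, min_node = NULL) {
  df <- as.data.frame(x)
  df$..y.. <- y
  # quantile-forest training samples node values through the R-level RNG,
  # so the whole call runs under the forest seed for bit-stable refits
  with_seed(seed, ranger::ranger(
    dependent.variable.name = "..y..", data = df,
    num.trees = num_trees,
    mtry = mtry %||% max(1L, floor(ncol(x) / 3)),
    min.node.size = min_node %||% if (quantreg) 20 else 5,
    importance = importance, quantreg = quantreg,
    seed = seed, num.threads = 1
  ))
}

oob_mse <- function(x, y, vars, num_trees, seeds) {
  errs <- vapply(seeds, function(s) {
    fit_forest(x[, vars, drop = FALSE], y, num_trees, seed = s)$prediction.error
  }, numeric(1))
  c(mean = mean(errs), sd = stats::sd(errs))
}

#' Three-step forest-based variable selection
#'
#' @param matrix A `covariate_matrix` (pruned), or a numeric predictor
#'   matrix with the response attached as attribute `response`.
#' @param n_forests Forests grown in the thresholding step.
#' @param n_forests_nested Forests per nested model in steps 2-3.
#' @param num_trees Trees per forest.
#' @param seed Integer seed; fixes every forest.
#' @return A `selection_result`: `ranking` (variable, mean/SD permutation
#'   importance, rank), `threshold`, the three nested sets `thresholded`,
#'   `interpretation`, `prediction`, OOB-error trajectories `oob_step2` /
#'   `oob_step3`, and `informative` (FALSE when nothing survives step 1).
#' @details Step 1 ranks variables by mean permutation importance over
#'   `n_forests` forests and discards those whose mean importance falls
#'   below the minimum of a regression-tree fit to the importance-SD-vs-rank
#'   curve (and any variable with non-positive mean importance). Step 2
#'   grows nested models along the ranking and keeps the smallest whose
#'   mean OOB MSE is within one SD (of the minimising model's OOB errors)
#'   of the minimum. Step 3 re-admits interpretation variables in rank
#'   order only when they reduce OOB MSE by more than the mean absolute
#'   fluctuation measured by adding known-noise variables to the model.
#' @export
select_variables <- function(matrix, n_forests = 50, n_forests_nested = 25,
                             num_trees = 100, seed = 1L) {
  x <- cm_predictors(matrix)
  y <- cm_response(matrix)
  stopifnot(!is.null(y), nrow(x) >= 10)
  with_seed(seed, {
    select_variables_impl(x, y, n_forests, n_forests_nested, num_trees)
  })
}

select_variables_impl <- function(x, y, n_forests, n_forests_nested,
                                  num_trees) {
  p <- ncol(x)
  seeds1 <- sample.int(.Machine$integer.max, n_forests)

  imp <- vapply(seeds1, function(s) {
    fit_forest(x, y, num_trees, seed = s, importance = "permutation")$
      variable.importance
  }, numeric(p))
  imp <- matrix(imp, nrow = p)   # vapply drops to a vector when p = 1
  mean_imp <- rowMeans(imp)
  sd_imp <- apply(imp, 1, stats::sd)
  ord <- order(mean_imp, decreasing = TRUE)
  ranking <- tibble::tibble(
    variable = colnames(x)[ord],
    mean_importance = mean_imp[ord],
    sd_importance = sd_imp[ord],
    rank = seq_len(p)
  )

  # data-driven threshold: minimum prediction of a regression tree fit to
  # the SD-vs-rank curve (SD of importance is low and flat in the pure-noise
  # tail, so its fitted minimum separates signal from noise)
  tree <- rpart::rpart(sd ~ rank,
                       data = data.frame(sd = ranking$sd_importance,
                                         rank = ranking$rank),
                       minsplit = 2, cp = 0.01)
  threshold <- min(stats::predict(tree))
  thresholded <- ranking$variable[ranking$mean_importance >= threshold &
                                    ranking$mean_importance > 0]

  empty <- function() structure(list(
    ranking = ranking, threshold = threshold,
    thresholded = character(), interpretation = character(),
    prediction = character(), oob_step2 = NULL, oob_step3 = NULL,
    informative = FALSE), class = "selection_result")
  if (length(thresholded) == 0) return(empty())

  seeds2 <- sample.int(.Machine$integer.max, n_forests_nested)
  nested <- t(vapply(seq_along(thresholded), function(j) {
    oob_mse(x, y, thresholded[seq_len(j)], num_trees, seeds2)
  }, numeric(2)))
  oob_step2 <- tibble::tibble(size = seq_along(thresholded),
                              variable = thresholded,
                              oob = nested[, "mean"], oob_sd = nested[, "sd"])
  jmin <- which.min(oob_step2$oob)
  cut <- oob_step2$oob[jmin] + oob_step2$oob_sd[jmin]
  jstar <- which(oob_step2$oob <= cut)[1]
  interpretation <- thresholded[seq_len(jstar)]

  # noise fluctuation: mean |delta OOB| from adding known-noise variables
  # (step-1 discards; failing that, post-interpretation leftovers) to the
  # interpretation model
  noise_pool <- setdiff(ranking$variable, thresholded)
  if (length(noise_pool) == 0) noise_pool <- setdiff(thresholded, interpretation)
  err_interp <- oob_mse(x, y, interpretation, num_trees, seeds2)["mean"]
  if (length(noise_pool) > 0) {
    probes <- utils::head(noise_pool, 10)
    deltas <- vapply(probes, function(v) {
      abs(oob_mse(x, y, c(interpretation, v), num_trees, seeds2)["mean"] -
            err_interp)
    }, numeric(1))
    fluct <- mean(deltas)
  } else {
    fluct <- oob_mse(x, y, interpretation, num_trees, seeds2)["sd"]
  }

  sel <- interpretation[1]
  err_cur <- oob_mse(x, y, sel, num_trees, seeds2)["mean"]
  steps <- tibble::tibble(variable = sel, oob = err_cur, admitted = TRUE)
  for (v in interpretation[-1]) {
    err_new <- oob_mse(x, y, c(sel, v), num_trees, seeds2)["mean"]
    admit <- (err_cur - err_new) > fluct
    steps <- dplyr::bind_rows(steps, tibble::tibble(
      variable = v, oob = err_new, admitted = admit))
    if (admit) { sel <- c(sel, v); err_cur <- err_new }
  }

  structure(list(
    ranking = ranking, threshold = threshold, thresholded = thresholded,
    interpretation = interpretation, prediction = sel,
    oob_step2 = oob_step2, oob_step3 = steps,
    noise_fluctuation = fluct, informative = TRUE
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  if (!x$informative) {
    cat("<selection_result> no informative predictors\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<selection_result> thresholded %d -> interpretation %d -> prediction %d\n",
    length(x$thresholded), length(x$interpretation), length(x$prediction)))
  cat("  prediction set:", paste(x$prediction, collapse = ", "), "\n")
  invisible(x)
}
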