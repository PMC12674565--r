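# Incremental sampling-effort experiment: how much does adding fractions of
# a new regional sample set improve local accuracy (held-out RMSE) and
# precision (mean quantile-forest SD at the held-out sites)?

#' Incremental sampling-effort calibration curve
#'
#' For each fraction f in `fractions` and each repeat, `floor(f * n)` new
#' regional sites are drawn at random (without replacement within a
#' repeat), a forest is trained on base + drawn sites, and the remaining
#' new sites are used to measure prediction RMSE and the mean predicted SD
#' ("spatial error"). At f = 1 all new sites enter training and evaluation
#' is in-sample on all of them, once, flagged as such.
#'
#' @param base A `covariate_matrix` (or predictor matrix with attribute
#'   `response`) of previously available sites; may have zero rows.
#' @param new Same type: the newly sampled regional sites (nonempty).
#' @param selected Optional covariate subset used by the model.
#' @param fractions Fractions of the new set to add (default 0 to 1 by
#'   0.1).
#' @param repeats Random draws per fraction below 1 (default 10).
#' @param n_trees Trees per forest.
#' @param seed Integer seed.
#' @return A `calibration_curve`: tibble with `fraction`, `repeat_id`,
#'   `n_train_new`, `n_eval`, `rmse`, `mean_sd`, `in_sample`.
#' @export
incremental_calibration <- function(base, new, selected = NULL,
                                    fractions = seq(0, 1, by = 0.1),
                                    repeats = 10, n_trees = 500,
                                    seed = 1L) {
  if (any(fractions < 0 | fractions > 1))
    stop("fractions must lie in [0, 1]")
  xb <- cm_predictors(base, selected); yb <- cm_response(base)
  xn <- cm_predictors(new, selected); yn <- cm_response(new)
  if (nrow(xn) == 0) stop("new regional data must be nonempty")
  if (is.null(yb)) yb <- numeric(0)
  n <- nrow(xn)

  with_seed(seed, {
    rows <- list()
    for (f in fractions) {
      reps <- if (f >= 1) 1L else repeats
      for (r in seq_len(reps)) {
        k <- floor(f * n)
        drawn <- if (k > 0) sample.int(n, k) else integer(0)
        eval_idx <- if (f >= 1) seq_len(n) else setdiff(seq_len(n), drawn)
        xtr <- rbind(xb, xn[drawn, , drop = FALSE])
        ytr <- c(yb, yn[drawn])
        stopifnot(length(intersect(drawn, eval_idx)) == 0 || f >= 1)
        if (nrow(xtr) == 0) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            fraction = f, repeat_id = r, n_train_new = k,
            n_eval = length(eval_idx), rmse = NA_real_, mean_sd = NA_real_,
            in_sample = FALSE)
          next
        }
        m <- fit_forest(xtr, ytr, num_trees = n_trees,
                        seed = sample.int(.Machine$integer.max, 1),
                        quantreg = TRUE)
        xe <- as.data.frame(xn[eval_idx, , drop = FALSE])
        pred <- stats::predict(m, data = xe, num.threads = 1)$predictions
        q <- stats::predict(m, data = xe, type = "quantiles",
                            quantiles = c(0.158655, 0.841345),
                            num.threads = 1)$predictions
        rows[[length(rows) + 1]] <- tibble::tibble(
          fraction = f, repeat_id = r, n_train_new = k,
          n_eval = length(eval_idx),
          rmse = sqrt(mean((pred - yn[eval_idx])^2)),
          mean_sd = mean((q[, 2] - q[, 1]) / 2),
          in_sample = f >= 1)
      }
    }
    structure(dplyr::bind_rows(rows), class = c("calibration_curve",
                                                "tbl_df", "tbl", "data.frame"))
  })
}

#' Summarise a calibration curve over repeats
#'
#' @param curve A `calibration_curve`.
#' @return Tibble with per-fraction mean/SD of RMSE and of the mean
#'   predicted SD.
#' @export
summarize_calibration <- function(curve) {
  curve |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(
      mean_rmse = mean(.data$rmse, na.rm = TRUE),
      sd_rmse = stats::sd(.data$rmse),
      mean_sd = mean(.data$mean_sd, na.rm = TRUE),
      n_repeats = dplyr::n(),
      in_sample = any(.data$in_sample),
      .groups = "drop")
}
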