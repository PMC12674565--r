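#!/usr/bin/env Rscript
# Fit the 3000-tree random-forest isoscape on the selected covariates,
# evaluate it by 10-fold CV repeated 5 times, compute node-impurity
# importance and partial dependence, and predict the ratio + SD surfaces
# over the full grid (SD from the 68.27% quantile-forest interval).
# Also scores the prediction against the known synthetic truth.

library(srisoscape)

world_dir <- "results/world"
samples <- read_sample_table(file.path(world_dir, "samples.csv"), "synthetic")
stack <- sapply(covariate_registry()$name, function(nm)
  read_raster(file.path(world_dir, paste0(nm, ".asc"))),
  simplify = FALSE)
cm <- extract_at_points(stack, samples)
sel <- jsonlite::read_json("results/selection_report.json",
                           simplifyVector = TRUE)$prediction

model <- fit_rf(cm, sel, n_trees = 3000, seed = 3)
print(model)
cv <- cross_validate(cm, sel, k = 10, repeats = 5, n_trees = 1000, seed = 4)
message(sprintf("CV (10-fold x 5): RMSE = %.5f, R2 = %.3f", cv$rmse, cv$r2))

imp <- importance_scores(model)
readr::write_csv(imp, "results/rf_importance.csv")
pd <- dplyr::bind_rows(lapply(sel, function(v)
  dplyr::mutate(partial_dependence(model, v), covariate = v)))
readr::write_csv(pd, "results/rf_partial_dependence.csv")

product <- predict_raster(model, stack)
write_isoscape(product, "results", "rf")

truth <- rg_values(read_raster(file.path(world_dir, "truth.asc")))
pred <- rg_values(product$prediction)
r2 <- 1 - sum((pred - truth)^2) / sum((truth - mean(truth))^2)
message(sprintf("raster-wide R2 against the synthetic truth: %.3f", r2))

jsonlite::write_json(
  list(n_trees = 3000, covariates = sel, cv_rmse = cv$rmse, cv_r2 = cv$r2,
       oob_mse = model$fit$prediction.error, truth_r2 = r2),
  "results/rf_metrics.json", auto_unbox = TRUE, pretty = TRUE)
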