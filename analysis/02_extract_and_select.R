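#!/usr/bin/env Rscript
# Covariate extraction at the sampling sites (nearest-valid-cell fallback
# within 50 km), correlation pruning at |R| > 0.9, and the three-step
# forest-based variable selection. Writes the covariate matrix, the
# pruning report and the selection report under results/.

library(srisoscape)

world_dir <- "results/world"
samples <- read_sample_table(file.path(world_dir, "samples.csv"), "synthetic")
stack <- sapply(covariate_registry()$name, function(nm)
  read_raster(file.path(world_dir, paste0(nm, ".asc"))),
  simplify = FALSE)

cm <- extract_at_points(stack, samples, max_fallback_km = 50)
print(cm)
readr::write_csv(cm$data, "results/covariate_matrix.csv")

pr <- prune_correlated(cm, threshold = 0.9)
message(sprintf("pruning kept %d of %d covariates (max |R| = %.3f)",
                length(pr$retained), length(cm$covariate_names),
                pr$max_abs_r))
print(pr$dropped)
jsonlite::write_json(list(retained = pr$retained, dropped = pr$dropped,
                          max_abs_r = pr$max_abs_r),
                     "results/pruning_report.json", auto_unbox = TRUE,
                     pretty = TRUE)

pruned <- cm
pruned$covariate_names <- pr$retained
sel <- select_variables(pruned, seed = 2)
print(sel)
jsonlite::write_json(list(threshold = sel$threshold,
                          thresholded = sel$thresholded,
                          interpretation = sel$interpretation,
                          prediction = sel$prediction,
                          ranking = sel$ranking),
                     "results/selection_report.json", auto_unbox = TRUE,
                     pretty = TRUE)
message("prediction set: ", paste(sel$prediction, collapse = ", "))
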