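test_that("oblique coordinates reduce to the axes at 0 and 90 degrees", {
  xy <- cbind(x = c(1, -2, 0.5), y = c(3, 1, -4))
  expect_equal(unname(oblique_coordinates(xy, 0)[, 1]), xy[, "x"])
  expect_equal(unname(oblique_coordinates(xy, 90)[, 1]), xy[, "y"])
  expect_equal(unname(oblique_coordinates(cbind(1, 1), 45)[1, 1]),
               sqrt(2), tolerance = 1e-12)
  expect_warning(o <- oblique_coordinates(xy, numeric(0)), "empty")
  expect_equal(ncol(o), 0)
  expect_error(oblique_coordinates(xy, 180), "\\[0, 180\\)")
})

test_that("a constant response flows through the stack unchanged", {
  set.seed(51)
  n <- 80
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(0.710, n)
  coords <- tibble::tibble(longitude = runif(n, 99, 100),
                           latitude = runif(n, 47, 48))
  suppressMessages(
    sm <- fit_stack(as_cm(x, y), coords,
                    stack_spec(k_folds = 4, rf_trees = 100, seed = 1)))
  pred <- predict(sm, x, coords)
  expect_equal(pred, rep(0.710, n), tolerance = 1e-6)
})

test_that("spatial folds hold out whole blocks and feed the meta-learner
           only out-of-fold predictions", {
  w <- test_world()
  cm <- test_matrix()
  idx <- 1:150
  sub <- cm; sub$data <- cm$data[idx, ]
  sm <- fit_stack(sub, w$samples[idx, ],
                  stack_spec(learners = c("rf", "glmnet"), k_folds = 4,
                             rf_trees = 100, seed = 2))
  folds <- sm$folds
  expect_equal(sort(unique(folds)), 1:4)
  # blocking oracle: folds are k-means cells in projected space, so every
  # point is nearer its own fold centroid than any other fold's
  xy <- project_local_km(w$samples$longitude[idx], w$samples$latitude[idx],
                         sm$center)
  cent <- sapply(1:4, function(f) colMeans(xy[folds == f, , drop = FALSE]))
  d2 <- sapply(1:4, function(f) (xy[, 1] - cent[1, f])^2 +
                 (xy[, 2] - cent[2, f])^2)
  expect_true(all(apply(d2, 1, which.min) == folds))
})

test_that("shuffled labels collapse the stack's spatially blocked CV R2", {
  w <- test_world()
  cm <- test_matrix()
  idx <- 1:150
  sub <- cm
  sub$data <- cm$data[idx, ]
  set.seed(99)
  sub$data$sr_ratio <- sample(sub$data$sr_ratio)  # break the signal
  suppressMessages(
    sm <- fit_stack(sub, w$samples[idx, ],
                    stack_spec(learners = c("rf", "glmnet", "svm"),
                               k_folds = 4, rf_trees = 100, seed = 3),
                    selected = c("r.m1", "r.mat", "r.map", "r.age")))
  expect_lte(sm$cv$stack["r2"], 0.1)
})

test_that("the stack is invariant under permutation of the learner list", {
  w <- test_world()
  cm <- test_matrix()
  idx <- 1:120
  sub <- cm; sub$data <- cm$data[idx, ]
  sel <- c("r.m1", "r.mat", "r.map")
  s1 <- fit_stack(sub, w$samples[idx, ],
                  stack_spec(learners = c("rf", "svm", "glmnet"),
                             k_folds = 3, rf_trees = 100, seed = 4),
                  selected = sel)
  s2 <- fit_stack(sub, w$samples[idx, ],
                  stack_spec(learners = c("glmnet", "rf", "svm"),
                             k_folds = 3, rf_trees = 100, seed = 4),
                  selected = sel)
  x <- cm_test <- as.matrix(sub$data[sel])
  p1 <- predict(s1, x, w$samples[idx, ])
  p2 <- predict(s2, x, w$samples[idx, ])
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("stack and RF isoscapes agree closely when the signal is
           covariate-driven", {
  w <- test_world()
  cm <- test_matrix()
  sel <- c("r.srsrq1", "r.age", "r.mat", "r.map")
  m_rf <- fit_rf(cm, sel, n_trees = 500, seed = 5)
  rf_prod <- predict_raster(m_rf, w$covariates)
  suppressMessages(
    sm <- fit_stack(cm, w$samples, stack_spec(rf_trees = 300, seed = 5),
                    selected = sel))
  eml_prod <- predict_raster_stack(sm, w$covariates)
  dif <- abs(rg_values(eml_prod$prediction) - rg_values(rf_prod$prediction))
  expect_lte(mean(dif), 0.001)
  # EML's uncertainty stays bounded where the RF uncertainty is extreme
  rf_sd <- rg_values(rf_prod$sd); eml_sd <- rg_values(eml_prod$sd)
  q99 <- stats::quantile(rf_sd, 0.99)
  expect_lte(stats::quantile(eml_sd, 0.99), q99 * 1.05)
})
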