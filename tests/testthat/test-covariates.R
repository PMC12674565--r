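test_that("a constant raster yields the constant at every site, flagged direct", {
  g <- const_raster(0.712, n = 8)
  ctr <- rg_cell_centers(g)
  sites <- tibble::tibble(id = c("a", "b"), longitude = ctr$x[c(2, 5)],
                          latitude = ctr$y[c(3, 7)])
  cm <- extract_at_points(list(cov = g), sites)
  expect_equal(cm$data$cov, c(0.712, 0.712))
  expect_true(all(cm$provenance == "direct"))
})

test_that("nodata cells fall back to the nearest valid cell (exhaustive oracle)", {
  set.seed(8)
  m <- matrix(runif(100, 0.705, 0.715), 10, 10)
  holes <- cbind(sample(10, 12, TRUE), sample(10, 12, TRUE))
  m[holes] <- NA
  g <- raster_grid(m, xmin = 100, ymax = 48, dx = 1 / 110.574)
  ctr <- rg_cell_centers(g)
  hole <- holes[1, ]
  sites <- tibble::tibble(id = "h", longitude = ctr$x[hole[2]],
                          latitude = ctr$y[hole[1]])
  cm <- extract_at_points(list(cov = g), sites, max_fallback_km = 50)
  expect_identical(unname(cm$provenance[1, "cov"]), "nearest-fallback")
  # oracle: scan every valid cell for the minimum great-circle distance
  valid <- which(!is.na(rg_values(g)), arr.ind = TRUE)
  d <- gc_distance_km(ctr$x[valid[, 2]], ctr$y[valid[, 1]],
                      sites$longitude, sites$latitude)
  best <- valid[which.min(d), ]
  expect_equal(cm$data$cov, m[best[1], best[2]])
  expect_lte(cm$fallback_km[1, "cov"], 50)
  expect_equal(unname(cm$fallback_km[1, "cov"]), min(d))
})

test_that("fallback beyond the search radius is a hard error naming the site", {
  m <- matrix(NA_real_, 10, 10); m[1, 1] <- 0.71
  g <- raster_grid(m, xmin = 100, ymax = 48, dx = 1 / 110.574)
  ctr <- rg_cell_centers(g)
  sites <- tibble::tibble(id = "far", longitude = ctr$x[10],
                          latitude = ctr$y[10])
  expect_error(extract_at_points(list(cov = g), sites, max_fallback_km = 2),
               "far")
  sites2 <- tibble::tibble(id = "out", longitude = 0, latitude = 0)
  expect_error(extract_at_points(list(cov = g), sites2), "out")
})

test_that("the full synthetic stack yields a sites x registry matrix", {
  w <- test_world()
  sites <- w$samples[1:100, ]
  cm <- extract_at_points(w$covariates, sites)
  reg <- covariate_registry()$name
  expect_equal(dim(cm$data[reg]), c(100, length(reg)))
  expect_identical(cm$covariate_names, reg)
  expect_false(anyNA(cm$data[reg]))
})

test_that("identical columns are pruned to one", {
  set.seed(1)
  a <- rnorm(100)
  x <- cbind(a = a, b = a, c = rnorm(100))
  pr <- prune_correlated(as_cm(x, rnorm(100)))
  expect_equal(sort(pr$retained), sort(setdiff(colnames(x), pr$dropped$variable)))
  expect_equal(nrow(pr$dropped), 1)
  expect_equal(pr$dropped$r, 1)
})

test_that("independent standard-normal columns survive pruning", {
  set.seed(123)
  x <- matrix(rnorm(500 * 3), 500, 3, dimnames = list(NULL, c("a", "b", "c")))
  pr <- prune_correlated(as_cm(x, rnorm(500)))
  expect_equal(sort(pr$retained), c("a", "b", "c"))
  expect_lte(pr$max_abs_r, 0.9)
})

test_that("a constructed R=0.95 pair collapses to one member; the pairwise
           contract is verified by full recomputation", {
  set.seed(7)
  n <- 400
  a <- rnorm(n)
  b <- 0.95 * a + sqrt(1 - 0.95^2) * rnorm(n)   # corr ~ 0.95
  x <- cbind(a = a, b = b, ind = rnorm(n))
  stopifnot(abs(cor(a, b)) > 0.9)
  pr <- prune_correlated(as_cm(x, rnorm(n)), threshold = 0.9)
  expect_true("ind" %in% pr$retained)
  expect_equal(length(intersect(c("a", "b"), pr$retained)), 1)
  r <- abs(cor(x[, pr$retained])); diag(r) <- 0
  expect_lte(max(r), 0.9)
})

test_that("zero-variance columns are dropped first with their own diagnostic", {
  set.seed(2)
  x <- cbind(flat = rep(1, 50), a = rnorm(50), b = rnorm(50))
  pr <- prune_correlated(as_cm(x, rnorm(50)))
  expect_true("flat" %in% pr$dropped$variable)
  expect_identical(pr$dropped$reason[pr$dropped$variable == "flat"],
                   "zero variance")
})
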