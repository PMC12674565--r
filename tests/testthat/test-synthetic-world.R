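test_that("single geology unit with zero noise and slopes gives a constant world", {
  cfg <- sim_config(grid_width = 12, grid_height = 12, n_geology_units = 1,
                    age_range = c(100, 100), climate_slopes = c(0, 0),
                    local_sd = 0, meas_sd = 0, n_sites = 20, seed = 3,
                    cluster_radius_km = 5)
  w <- generate_world(cfg)
  truth <- rg_values(w$truth)
  expected <- cfg$intercept + cfg$age_slope * log10(100)
  expect_equal(unname(truth), matrix(expected, 12, 12))
  expect_equal(w$samples$sr_ratio, rep(expected, 20))
})

test_that("identical seeds give identical worlds; different seeds differ", {
  cfg <- sim_config(grid_width = 20, grid_height = 20, n_sites = 30, seed = 9,
                    cluster_radius_km = 5)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$truth$values, w2$truth$values)
  expect_identical(w1$samples, w2$samples)
  cfg2 <- sim_config(grid_width = 20, grid_height = 20, n_sites = 30,
                     seed = 10, cluster_radius_km = 5)
  w3 <- generate_world(cfg2)
  expect_false(identical(w1$geology$values, w3$geology$values))
})

test_that("older units carry higher true ratios (brute-force per-unit means)", {
  cfg <- sim_config(grid_width = 30, grid_height = 30, n_geology_units = 6,
                    climate_slopes = c(0, 0), local_sd = 0, meas_sd = 0,
                    n_sites = 0, seed = 21, cluster_radius_km = 5)
  w <- generate_world(cfg)
  units <- as.vector(w$geology$values)
  truth <- as.vector(rg_values(w$truth))
  ages <- tapply(as.vector(w$covariates$r.meanage_geol$values), units, mean)
  means <- tapply(truth, units, mean)
  ord <- order(ages)
  expect_true(all(diff(means[ord]) > 0))
})

test_that("zero-noise samples reproduce the raster truth exactly", {
  cfg <- sim_config(grid_width = 25, grid_height = 25, local_sd = 0,
                    meas_sd = 0, n_sites = 60, seed = 4,
                    cluster_radius_km = 8)
  w <- generate_world(cfg)
  at_cell <- w$truth$values[cbind(w$samples$cell_row, w$samples$cell_col)]
  expect_identical(w$samples$sr_ratio, at_cell)
  expect_identical(w$samples$true_ratio, at_cell)
})

test_that("clustered sampling respects the disc radius (distance-scan oracle)", {
  w <- test_world()
  s <- sample_sites(w, 80, clustering_fraction = 1, cluster_radius_km = 10,
                    seed = 6)
  ctr <- attr(s, "cluster_center")
  d <- gc_distance_km(s$longitude, s$latitude, ctr["lon"], ctr["lat"])
  # cells are selected by centre membership in the disc, so every site's
  # cell centre must lie within the radius
  expect_true(all(d <= 10))
  expect_equal(nrow(sample_sites(w, 0, seed = 1)), 0)
  expect_error(sample_sites(w, 10, cluster_radius_km = 1e5, seed = 1),
               "exceeds")
})

test_that("a larger age slope increases between-unit variance of the truth", {
  for (seed in 1:10) {
    mk <- function(slope) {
      cfg <- sim_config(grid_width = 20, grid_height = 20,
                        n_geology_units = 5, age_slope = slope,
                        climate_slopes = c(0, 0), local_sd = 0, meas_sd = 0,
                        n_sites = 0, seed = seed, cluster_radius_km = 5)
      w <- generate_world(cfg)
      stats::var(tapply(as.vector(w$truth$values),
                        as.vector(w$geology$values), mean))
    }
    expect_lt(mk(0.001), mk(0.004))
  }
})

test_that("worlds serialise to disk and read back", {
  w <- generate_world(sim_config(grid_width = 15, grid_height = 15,
                                 n_sites = 10, seed = 2,
                                 cluster_radius_km = 5))
  d <- file.path(tempdir(), "worlddir")
  write_world(w, d)
  expect_true(file.exists(file.path(d, "r.m1.asc")))
  g <- read_raster(file.path(d, "truth.asc"))
  expect_equal(g$values, w$truth$values, tolerance = 1e-12)
})
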