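mk_product <- function(pred, sd = NULL) {
  if (is.null(sd))
    sd <- raster_grid(matrix(0, nrow(pred$values), ncol(pred$values)),
                      xmin = pred$xmin, ymax = pred$ymax, dx = pred$dx)
  structure(list(prediction = pred, sd = sd, metadata = list(model = "test")),
            class = "isoscape_product")
}

test_that("the local range over a constant field is the constant", {
  g <- const_raster(0.710, n = 12)
  ctr <- rg_cell_centers(g)
  for (r in c(1, 10, 50))
    expect_equal(unname(local_range(g, ctr$x[6], ctr$y[6], r)),
                 c(0.710, 0.710))
})

test_that("local ranges match an exhaustive cell-centre scan", {
  set.seed(61)
  n <- 40
  m <- matrix(runif(n * n, 0.705, 0.720), n, n)
  m[sample(n * n, 30)] <- NA      # nodata must be ignored
  g <- raster_grid(m, xmin = 100, ymax = 48, dx = 1 / 110.574)
  ctr <- rg_cell_centers(g)
  for (i in 1:5) {
    lon <- runif(1, 100.05, 100.3); lat <- runif(1, 47.7, 47.95)
    r <- runif(1, 2, 12)
    got <- local_range(g, lon, lat, r)
    # oracle: scan every cell centre
    vals <- c()
    for (row in 1:n) for (col in 1:n) {
      if (is.na(rg_values(g)[row, col])) next
      if (gc_distance_km(ctr$x[col], ctr$y[row], lon, lat) <= r)
        vals <- c(vals, m[row, col])
    }
    expect_identical(unname(got), c(min(vals), max(vals)))
  }
})

test_that("a sub-cell radius returns the single containing cell's value", {
  set.seed(3)
  m <- matrix(runif(25, 0.705, 0.715), 5, 5)
  g <- raster_grid(m, xmin = 100, ymax = 48, dx = 1 / 110.574)
  ctr <- rg_cell_centers(g)
  got <- local_range(g, ctr$x[3], ctr$y[2], 0.3)   # < half a ~1 km cell
  expect_equal(unname(got), rep(m[2, 3], 2))
  expect_error(local_range(g, 0, 0, 10), "outside")
  # a point off the cell centre with a sub-centre-distance radius captures
  # no cell centre at all
  expect_error(local_range(g, ctr$x[1] + 0.45 * g$dx, ctr$y[1], 1e-3),
               "no valid cell")
})

test_that("site samples pool into per-group arithmetic means", {
  df <- tibble::tibble(
    site = c("A", "A", "A", "A", "B"),
    longitude = 100, latitude = 47,
    material = c("human", "human", "human", "animal", "plant"),
    period = c("LBA", "LBA", "modern", "LBA", NA),
    sr_ratio = c(0.710, 0.712, 0.709, 0.715, 0.708),
    source = c("s1", "s2", "s1", "s1", "s1"),
    coord_provenance = "exact")
  pooled <- pool_site_samples(site_table(df))
  hA <- pooled[pooled$site == "A" & pooled$material == "human" &
                 pooled$epoch_class == "archaeological", ]
  expect_equal(hA$mean_ratio, 0.711)     # pooled across source studies
  expect_equal(hA$n, 2)
  mA <- pooled[pooled$site == "A" & pooled$epoch_class == "modern", ]
  expect_equal(mA$mean_ratio, 0.709)
  expect_equal(pooled$mean_ratio[pooled$site == "B"], 0.708)
  # group-by oracle: pooled n adds up to the raw row count
  expect_equal(sum(pooled$n), nrow(df))
})

test_that("13 of 14 samples inside the local range reports 92.86 percent", {
  g <- const_raster(0.710, n = 30)
  ctr <- rg_cell_centers(g)
  df <- tibble::tibble(
    site = "bb",
    longitude = ctr$x[15], latitude = ctr$y[15],
    material = "human", period = "Han",
    sr_ratio = c(rep(0.710, 13), 0.7125),
    source = "s", coord_provenance = "exact")
  out <- assess_sites(mk_product(g), site_table(df), radii_km = c(10, 20, 50))
  expect_equal(out$n, 14)
  expect_equal(out$prop_10km, 92.86)
  expect_equal(out$prop_20km, 92.86)
  # the one outlier pulls the mean 0.00018 above the (point) local range
  expect_false(out$mean_within_50km)
  expect_identical(out$deviation_category, "small")
})

test_that("all-local samples give 100.00 at every radius", {
  g <- const_raster(0.710, n = 20)
  ctr <- rg_cell_centers(g)
  df <- tibble::tibble(site = "s", longitude = ctr$x[10], latitude = ctr$y[10],
                       material = "animal", period = "LBA",
                       sr_ratio = rep(0.710, 6),
                       source = "s", coord_provenance = "exact")
  out <- assess_sites(mk_product(g), site_table(df))
  expect_equal(unlist(out[paste0("prop_", c(10, 20, 50), "km")]),
               c(prop_10km = 100, prop_20km = 100, prop_50km = 100))
  expect_identical(out$deviation_category, "inside")
  expect_equal(out$deviation, 0)
})

test_that("widening the radius onto a low-ratio unit keeps proportions
           non-decreasing (exhaustive recomputation)", {
  # inner disc (<= ~12 km) at 0.710; beyond it a lower-ratio unit at 0.705
  n <- 50
  g0 <- const_raster(0.710, n = n)
  ctr <- rg_cell_centers(g0)
  clon <- ctr$x[25]; clat <- ctr$y[25]
  m <- matrix(0.710, n, n)
  for (row in 1:n) for (col in 1:n)
    if (gc_distance_km(ctr$x[col], ctr$y[row], clon, clat) > 12)
      m[row, col] <- 0.705
  g <- raster_grid(m, xmin = g0$xmin, ymax = g0$ymax, dx = g0$dx)
  df <- tibble::tibble(site = "s", longitude = clon, latitude = clat,
                       material = "human", period = "LBA",
                       sr_ratio = c(0.710, 0.7051, 0.7090),
                       source = "s", coord_provenance = "exact")
  out <- assess_sites(mk_product(g), site_table(df), radii_km = c(10, 20, 50))
  props <- unlist(out[paste0("prop_", c(10, 20, 50), "km")])
  expect_true(all(diff(props) >= 0))
  # oracle at each radius
  for (r in c(10, 20, 50)) {
    rng <- local_range(g, clon, clat, r)
    within <- df$sr_ratio >= rng["min"] & df$sr_ratio <= rng["max"]
    expect_equal(unname(props[paste0("prop_", r, "km")]),
                 floor(100 * mean(within) * 100 + 0.5) / 100)
  }
  # 10 km: point range at 0.710, only the first sample is inside; at 20
  # and 50 km the range widens to [0.705, 0.710] and admits all three
  expect_equal(unname(props), c(floor(100 / 3 * 100 + 0.5) / 100, 100, 100))
})

test_that("group means off the local range are classified by deviation size", {
  g <- const_raster(0.710, n = 20)
  ctr <- rg_cell_centers(g)
  mk <- function(vals) tibble::tibble(
    site = "s", longitude = ctr$x[10], latitude = ctr$y[10],
    material = "human", period = "LBA", sr_ratio = vals,
    source = "s", coord_provenance = "exact")
  small <- assess_sites(mk_product(g), site_table(mk(0.710 + 0.0003)))
  expect_identical(small$deviation_category, "small")
  expect_equal(small$deviation, 0.0003)
  mod <- assess_sites(mk_product(g), site_table(mk(0.710 + 0.0008)))
  expect_identical(mod$deviation_category, "moderate")
  large <- assess_sites(mk_product(g), site_table(mk(0.710 - 0.002)))
  expect_identical(large$deviation_category, "large")
})
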