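# Synthetic landscapes for testing the isoscape pipeline end to end.
#
# The generator emulates the statistical structure the analysis assumes:
# piecewise geology (sharp unit boundaries) whose formation age drives the
# true bioavailable ratio, smooth autocorrelated environmental fields, a
# spatially clustered sampling campaign (dense in one "province", sparse
# elsewhere), and additive local + measurement noise. It makes no attempt
# at geochemical realism; it exists so every pipeline stage has a known
# ground truth.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All randomness in the package funnels through this.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configuration for a synthetic strontium landscape
#'
#' Defaults describe the study conditions used throughout the package's
#' simulation experiments: a 100 x 100 cell grid of ~1 km cells, a dozen
#' geological units with formation ages spanning 1-3000 Myr (Archean
#' basement to Cenozoic cover), two autocorrelated climate fields entering
#' the response, a local (within-site environmental) noise of 0.001 and a
#' measurement noise of 0.0001 on the ratio scale, and 500 sampling sites
#' of which 60% fall in one dense 15 km-radius cluster.
#'
#' @param grid_width,grid_height Grid dimensions in cells (>= 2).
#' @param cell_km Nominal cell size in km (converted to degrees at the
#'   reference latitude; the grid is square in degrees).
#' @param n_geology_units Number of Voronoi geology units.
#' @param age_range Unit formation-age range in Myr; ages are drawn
#'   log-uniformly over it.
#' @param n_climate_fields Number of smooth climate fields entering the
#'   response.
#' @param autocorr_km Autocorrelation length of the smooth fields, km.
#' @param intercept Baseline ratio (young, Rb-poor lithology end member).
#' @param age_slope Ratio increase per log10(Myr) of unit age.
#' @param climate_slopes Ratio contribution per SD of each climate field
#'   (recycled to `n_climate_fields`).
#' @param local_sd Site-level environmental noise SD, ratio units.
#' @param meas_sd Mass-spectrometry measurement noise SD, ratio units.
#' @param n_sites Number of sampling sites.
#' @param clustering_fraction Fraction of sites inside the dense cluster.
#' @param cluster_radius_km Radius of the dense cluster, km.
#' @param origin_lon,origin_lat Geographic position of the grid's top-left
#'   corner (degrees, WGS84).
#' @param seed Integer seed fixing every random draw.
#' @return A `sim_config` list.
#' @export
sim_config <- function(grid_width = 100, grid_height = 100, cell_km = 1,
                       n_geology_units = 12, age_range = c(1, 3000),
                       n_climate_fields = 2, autocorr_km = 20,
                       intercept = 0.704, age_slope = 0.002,
                       climate_slopes = c(0.0008, 0.0005),
                       local_sd = 0.001, meas_sd = 1e-4,
                       n_sites = 500, clustering_fraction = 0.6,
                       cluster_radius_km = 15,
                       origin_lon = 99, origin_lat = 49, seed = 1L) {
  if (grid_width < 2 || grid_height < 2)
    stop("degenerate grid: need at least 2 cells per side")
  stopifnot(local_sd >= 0, meas_sd >= 0, n_sites >= 0,
            n_geology_units >= 1, cell_km > 0,
            length(age_range) == 2, age_range[1] > 0,
            age_range[2] >= age_range[1],
            clustering_fraction >= 0, clustering_fraction <= 1)
  climate_slopes <- rep_len(climate_slopes, n_climate_fields)
  structure(list(
    grid_width = grid_width, grid_height = grid_height, cell_km = cell_km,
    n_geology_units = n_geology_units, age_range = age_range,
    n_climate_fields = n_climate_fields, autocorr_km = autocorr_km,
    intercept = intercept, age_slope = age_slope,
    climate_slopes = climate_slopes, local_sd = local_sd, meas_sd = meas_sd,
    n_sites = n_sites, clustering_fraction = clustering_fraction,
    cluster_radius_km = cluster_radius_km,
    origin_lon = origin_lon, origin_lat = origin_lat, seed = as.integer(seed)
  ), class = "sim_config")
}

# Gaussian random field on an nr x nc grid: white noise smoothed by a
# separable Gaussian kernel (sd in cells), standardised to mean 0, sd 1.
gaussian_field <- function(nr, nc, sd_cells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sd_cells > 0) {
    smoother <- function(n) {
      idx <- seq_len(n)
      k <- outer(idx, idx, function(i, j) stats::dnorm(i - j, sd = sd_cells))
      k / rowSums(k)
    }
    z <- smoother(nr) %*% z %*% t(smoother(nc))
  }
  s <- stats::sd(z)
  if (s > 0) (z - mean(z)) / s else z - mean(z)
}

#' Generate a synthetic strontium landscape
#'
#' Builds a Voronoi-tessellated geology raster with log-uniform unit ages,
#' smooth climate fields, the full covariate stack named after
#' [covariate_registry()], the true isoscape
#' `intercept + age_slope * log10(age) + sum(slope_i * climate_i)`,
#' and a clustered sampling campaign. Identical seeds give bit-identical
#' worlds.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_world`: list with `config`, `geology` (unit-label
#'   raster), `truth` (true isoscape raster), `covariates` (named list of
#'   rasters, one per registry entry), and `samples` (tibble of site
#'   records incl. the generating truth).
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_world_impl(config))
}

generate_world_impl <- function(cfg) {
  nr <- cfg$grid_height; nc <- cfg$grid_width
  cell_deg <- cfg$cell_km / 110.574   # degrees of latitude per km
  grid0 <- function(m) raster_grid(m, xmin = cfg$origin_lon,
                                   ymax = cfg$origin_lat, dx = cell_deg)

  # Voronoi geology: nearest uniformly placed seed, Euclidean in cell space
  seeds <- cbind(row = stats::runif(cfg$n_geology_units, 0.5, nr + 0.5),
                 col = stats::runif(cfg$n_geology_units, 0.5, nc + 0.5))
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  best_d <- matrix(Inf, nr, nc); unit <- matrix(1L, nr, nc)
  for (u in seq_len(cfg$n_geology_units)) {
    d <- (rows - seeds[u, 1])^2 + (cols - seeds[u, 2])^2
    take <- d < best_d
    unit[take] <- u
    best_d[take] <- d[take]
  }
  log_age <- stats::runif(cfg$n_geology_units,
                          log10(cfg$age_range[1]), log10(cfg$age_range[2]))
  age <- 10^log_age
  age_r <- matrix(age[unit], nr, nc)

  sd_cells <- cfg$autocorr_km / cfg$cell_km
  climate <- lapply(seq_len(cfg$n_climate_fields),
                    function(i) gaussian_field(nr, nc, sd_cells))

  truth <- matrix(cfg$intercept + cfg$age_slope * log10(age_r), nr, nc)
  for (i in seq_along(climate))
    truth <- truth + cfg$climate_slopes[i] * climate[[i]]
  if (any(truth <= 0.702) || any(truth >= 0.760))
    stop("true isoscape left the plausible (0.702, 0.760) window; ",
         "reduce slopes or the age range")

  # Covariate stack over the full registry. Bedrock-model quantiles are
  # noisy transforms of the age-driven bedrock ratio; lithological ages are
  # per-unit perturbations of the true age; r.mat / r.map are the response
  # climate fields on realistic scales; everything else is an independent
  # smooth field with registry-appropriate offset and scale.
  bedrock <- cfg$intercept + cfg$age_slope * log10(age_r)
  perturb <- function(scale) scale * gaussian_field(nr, nc, sd_cells)
  cov <- list(
    r.m1 = bedrock + perturb(2e-4),
    r.srsrq1 = bedrock - 0.0012 + perturb(2e-4),
    r.srsrq3 = bedrock + 0.0012 + perturb(2e-4),
    r.meanage_geol = age_r,
    r.minage_geol = matrix((age * stats::runif(length(age), 0.6, 0.9))[unit], nr, nc),
    r.maxage_geol = matrix((age * stats::runif(length(age), 1.1, 1.6))[unit], nr, nc),
    r.age = matrix((age * stats::runif(length(age), 0.8, 1.2))[unit], nr, nc)
  )
  clim_names <- c("r.mat", "r.map")
  clim_scale <- list(c(0, 4), c(250, 80))    # deg C; mm/yr
  for (i in seq_len(cfg$n_climate_fields)) {
    nm <- if (i <= 2) clim_names[i] else sprintf("r.clim%02d", i)
    sc <- if (i <= 2) clim_scale[[i]] else c(0, 1)
    cov[[nm]] <- sc[1] + sc[2] * climate[[i]]
  }
  noise_spec <- list(
    r.pet = c(900, 150), r.ai = c(0.3, 0.1), r.salt = c(0.5, 0.2),
    r.dust = c(2, 0.8), r.fire = c(1e-12, 4e-13), r.foss = c(5e-13, 2e-13),
    r.volc = c(1e-13, 4e-14), r.dist = c(1500, 300),
    r.elevation = c(1500, 400), r.bouguer = c(-150, 40), r.GUM = c(5, 2),
    r.cec = c(180, 50), r.ph = c(70, 8), r.phkcl = c(60, 8),
    r.clay = c(200, 60), r.ocs = c(60, 20), r.bulk = c(130, 15)
  )
  for (nm in setdiff(covariate_registry()$name, names(cov)))
    cov[[nm]] <- noise_spec[[nm]][1] + noise_spec[[nm]][2] *
      gaussian_field(nr, nc, sd_cells)

  world <- structure(list(
    config = cfg,
    geology = grid0(unit + 0),
    truth = grid0(truth),
    covariates = lapply(cov[covariate_registry()$name], grid0),
    samples = NULL
  ), class = "synthetic_world")
  world$samples <- sample_sites_impl(world, cfg$n_sites,
                                     cfg$clustering_fraction,
                                     cfg$cluster_radius_km,
                                     cfg$local_sd, cfg$meas_sd)
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_world> %d x %d cells, %d geology units, %d covariates, ",
    "%d samples\n"),
    nrow(x$truth$values), ncol(x$truth$values),
    x$config$n_geology_units, length(x$covariates), nrow(x$samples)))
  invisible(x)
}

#' Draw a clustered sampling campaign over a synthetic world
#'
#' A fraction of sites falls inside one randomly centred disc (the densely
#' sampled province); the remainder is uniform over the grid. Each record
#' carries the generating cell's true ratio so recovery tests can compare
#' against truth. Recorded ratio = truth + local noise + measurement noise.
#'
#' @param world A `synthetic_world`.
#' @param n Number of sites (>= 0).
#' @param clustering_fraction Fraction of sites inside the cluster disc.
#' @param cluster_radius_km Disc radius, km (must fit inside the grid).
#' @param seed Integer seed.
#' @param local_sd,meas_sd Noise SDs; default to the world's config.
#' @return Tibble of synthetic sample records.
#' @export
sample_sites <- function(world, n, clustering_fraction = 0.6,
                         cluster_radius_km = 15, seed = 1L,
                         local_sd = world$config$local_sd,
                         meas_sd = world$config$meas_sd) {
  with_seed(seed, sample_sites_impl(world, n, clustering_fraction,
                                    cluster_radius_km, local_sd, meas_sd))
}

sample_sites_impl <- function(world, n, clustering_fraction,
                              cluster_radius_km, local_sd, meas_sd) {
  stopifnot(n >= 0)
  cfg <- world$config
  truth <- world$truth
  nr <- nrow(truth$values); nc <- ncol(truth$values)
  ctr <- rg_cell_centers(truth)
  if (n == 0) return(empty_samples())

  extent_km <- min(nr, nc) * cfg$cell_km
  if (cluster_radius_km > extent_km)
    stop("cluster radius (", cluster_radius_km,
         " km) exceeds the grid extent (", extent_km, " km)")

  n_clust <- round(n * clustering_fraction)
  crow <- sample.int(nr, 1); ccol <- sample.int(nc, 1)
  clon <- ctr$x[ccol]; clat <- ctr$y[crow]

  # cells whose centres lie within the disc (great-circle)
  cell_lon <- rep(ctr$x, each = nr); cell_lat <- rep(ctr$y, times = nc)
  d <- gc_distance_km(cell_lon, cell_lat, clon, clat)
  in_disc <- which(d <= cluster_radius_km)
  if (length(in_disc) == 0) in_disc <- (ccol - 1) * nr + crow

  pick_clust <- in_disc[sample.int(length(in_disc), n_clust, replace = TRUE)]
  pick_unif <- sample.int(nr * nc, n - n_clust, replace = TRUE)
  idx <- c(pick_clust, pick_unif)
  row <- ((idx - 1) %% nr) + 1
  col <- ((idx - 1) %/% nr) + 1

  tval <- truth$values[cbind(row, col)]
  ratio <- tval + stats::rnorm(n, 0, local_sd) + stats::rnorm(n, 0, meas_sd)
  out <- tibble::tibble(
    id = sprintf("syn%04d", seq_len(n)),
    longitude = ctr$x[col],
    latitude = ctr$y[row],
    material = "plant",
    sr_ratio = ratio,
    sr_2sigma = 2 * meas_sd,
    true_ratio = tval,
    cell_row = row,
    cell_col = col,
    clustered = seq_len(n) <= n_clust
  )
  attr(out, "cluster_center") <- c(lon = clon, lat = clat,
                                   radius_km = cluster_radius_km)
  out
}

empty_samples <- function() {
  tibble::tibble(id = character(), longitude = numeric(), latitude = numeric(),
                 material = character(), sr_ratio = numeric(),
                 sr_2sigma = numeric(), true_ratio = numeric(),
                 cell_row = integer(), cell_col = integer(),
                 clustered = logical())
}

#' Write a synthetic world to disk
#'
#' Covariates, truth and geology go to ESRI ASCII rasters; samples to a
#' CSV in the synthetic sample-table schema.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(world$covariates))
    write_raster(world$covariates[[nm]], file.path(dir, paste0(nm, ".asc")))
  write_raster(world$truth, file.path(dir, "truth.asc"))
  write_raster(world$geology, file.path(dir, "geology.asc"))
  write_sample_table(world$samples, file.path(dir, "samples.csv"))
  invisible(dir)
}
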