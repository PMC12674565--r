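# Buffer-based local/non-local assessment: compare measured ratios at a
# site against the range the isoscape predicts within 10/20/50 km, count
# the samples falling inside, and classify how far each group mean sits
# from the local baseline.

#' Predicted-ratio range within a radius of a site
#'
#' Minimum and maximum of the prediction surface over all valid cells whose
#' centres lie within the great-circle radius of the site. Nodata cells are
#' ignored; a radius capturing no valid cell is an explicit error.
#'
#' @param product An `isoscape_product` (or a single `raster_grid`).
#' @param lon,lat Site coordinates, decimal degrees.
#' @param radius_km Buffer radius in km (> 0).
#' @param site Optional label used in error messages.
#' @return Named numeric `c(min, max)`.
#' @export
local_range <- function(product, lon, lat, radius_km, site = "site") {
  if (radius_km <= 0) stop("radius must be positive")
  grid <- if (inherits(product, "isoscape_product")) product$prediction
          else product
  if (is.null(rg_cell_at(grid, lon, lat)))
    stop("site '", site, "' lies outside the isoscape extent")
  v <- rg_values(grid)
  ctr <- rg_cell_centers(grid)
  nr <- nrow(v)
  valid <- which(!is.na(v), arr.ind = TRUE)
  if (nrow(valid) == 0) stop("isoscape has no valid cells")
  d <- gc_distance_km(ctr$x[valid[, 2]], ctr$y[valid[, 1]], lon, lat)
  inside <- d <= radius_km
  if (!any(inside))
    stop("no valid cell centre within ", radius_km, " km of site '",
         site, "'")
  vals <- v[valid[inside, , drop = FALSE]]
  c(min = min(vals), max = max(vals))
}

#' Pool site samples into group means
#'
#' Measurements from different source studies are pooled per site; means
#' are computed per (site, material, epoch class), with archaeological and
#' modern samples pooled separately. The epoch class is `"modern"` when
#' the period is "modern" (case-insensitive), `"archaeological"`
#' otherwise.
#'
#' @param sites A `site_table` (or its `samples` tibble).
#' @return Tibble with `site`, `material`, `epoch_class`, `periods`,
#'   `n`, `mean_ratio`.
#' @export
pool_site_samples <- function(sites) {
  samples <- if (inherits(sites, "site_table")) sites$samples else sites
  samples |>
    dplyr::mutate(epoch_class = ifelse(
      !is.na(.data$period) & tolower(.data$period) == "modern",
      "modern", "archaeological")) |>
    dplyr::group_by(.data$site, .data$material, .data$epoch_class) |>
    dplyr::summarise(
      periods = paste(unique(stats::na.omit(.data$period)), collapse = ", "),
      n = dplyr::n(),
      mean_ratio = mean(.data$sr_ratio),
      .groups = "drop")
}

classify_deviation <- function(dev) {
  dplyr::case_when(
    dev == 0 ~ "inside",
    dev < 0.0005 ~ "small",
    dev <= 0.001 ~ "moderate",
    TRUE ~ "large"
  )
}

#' Assess site samples against an isoscape
#'
#' For every site group (site x material x epoch class): the predicted
#' ratio range within each radius, the share of samples falling inside it
#' (closed interval, percent, two decimals, half-up), the group mean and
#' whether it falls inside, and — at the largest radius — the deviation of
#' the mean from the nearest range bound with its category
#' (`inside` / `small` < 0.0005 / `moderate` / `large` > 0.001).
#'
#' @param product An `isoscape_product`.
#' @param sites A `site_table`.
#' @param radii_km Buffer radii in km (default 10/20/50).
#' @return A tibble (one row per group) with `prop_<r>km`,
#'   `mean_within_<r>km` columns per radius, plus `deviation` and
#'   `deviation_category`; the per-site ranges are attached as attribute
#'   `ranges` (tibble: site, radius_km, range_min, range_max).
#' @export
assess_sites <- function(product, sites, radii_km = c(10, 20, 50)) {
  stopifnot(inherits(sites, "site_table"))
  radii_km <- sort(radii_km)
  if (!identical(product$prediction$crs, "EPSG:4326") &&
      !grepl("4326|WGS84", product$prediction$crs, ignore.case = TRUE))
    warning("isoscape CRS is '", product$prediction$crs,
            "'; site coordinates are assumed to be in the same CRS")

  ranges <- purrr::map_dfr(seq_len(nrow(sites$sites)), function(i) {
    s <- sites$sites[i, ]
    purrr::map_dfr(radii_km, function(r) {
      rng <- local_range(product, s$longitude, s$latitude, r, site = s$site)
      tibble::tibble(site = s$site, radius_km = r,
                     range_min = rng["min"], range_max = rng["max"])
    })
  })
  # interval nesting is structural (larger radius = superset of cells);
  # assert it anyway
  chk <- ranges |>
    dplyr::group_by(.data$site) |>
    dplyr::arrange(.data$radius_km, .by_group = TRUE) |>
    dplyr::summarise(ok = all(diff(.data$range_min) <= 1e-12) &&
                       all(diff(.data$range_max) >= -1e-12),
                     .groups = "drop")
  stopifnot(all(chk$ok))

  groups <- pool_site_samples(sites)
  samples <- sites$samples |>
    dplyr::mutate(epoch_class = ifelse(
      !is.na(.data$period) & tolower(.data$period) == "modern",
      "modern", "archaeological"))

  out <- purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sm <- samples[samples$site == g$site & samples$material == g$material &
                    samples$epoch_class == g$epoch_class, ]
    site_info <- sites$sites[sites$sites$site == g$site, ]
    row <- tibble::tibble(
      site = g$site, material = g$material, epoch_class = g$epoch_class,
      periods = g$periods, n = g$n, mean_ratio = g$mean_ratio,
      coord_provenance = site_info$coord_provenance,
      summary_only = site_info$summary_only)
    rmax <- max(radii_km)
    for (r in radii_km) {
      rng <- ranges[ranges$site == g$site & ranges$radius_km == r, ]
      within <- sm$sr_ratio >= rng$range_min & sm$sr_ratio <= rng$range_max
      row[[sprintf("prop_%dkm", r)]] <-
        if (site_info$summary_only) NA_real_
        else round_half_up(100 * mean(within), 2)
      row[[sprintf("mean_within_%dkm", r)]] <-
        g$mean_ratio >= rng$range_min & g$mean_ratio <= rng$range_max
      if (r == rmax) {
        dev <- if (row[[sprintf("mean_within_%dkm", r)]]) 0
        else min(abs(g$mean_ratio - rng$range_min),
                 abs(g$mean_ratio - rng$range_max))
        row$deviation <- dev
        row$deviation_category <- classify_deviation(dev)
      }
    }
    row
  })
  attr(out, "ranges") <- ranges
  attr(out, "radii_km") <- radii_km
  out
}

#' Site assessment from deposited isoscape products
#'
#' Runs the full buffer assessment against a deposited prediction/SD
#' raster pair and a compiled site table, and summarises the headline
#' counts: sites whose group mean falls within the 50 km and 10 km local
#' ranges, and human-remain sites with a majority of samples local within
#' 50 km. `dir` must contain `rf_prediction.asc`, `rf_sd.asc` and
#' `sites_sm2.csv` (sm2 schema).
#'
#' @param dir Directory holding the deposited products.
#' @param radii_km Buffer radii.
#' @return List: `assessment` (the per-group table), `n_sites`,
#'   `sites_mean_within_50km`, `sites_mean_within_10km`,
#'   `human_sites_majority_local_50km`, `n_human_sites`.
#' @export
reproduce_published_assessment <- function(dir, radii_km = c(10, 20, 50)) {
  pred <- read_raster(file.path(dir, "rf_prediction.asc"))
  sdg <- read_raster(file.path(dir, "rf_sd.asc"))
  product <- structure(list(prediction = pred, sd = sdg,
                            metadata = list(model = "rf-deposited")),
                       class = "isoscape_product")
  st <- read_sample_table(file.path(dir, "sites_sm2.csv"), "sm2")
  assessment <- assess_sites(product, st, radii_km)
  arch <- assessment[assessment$epoch_class == "archaeological", ]
  rmax <- max(radii_km); rmin <- min(radii_km)
  per_site <- arch |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(
      within_max = any(.data[[sprintf("mean_within_%dkm", rmax)]]),
      within_min = any(.data[[sprintf("mean_within_%dkm", rmin)]]),
      .groups = "drop")
  human <- arch[arch$material == "human", ]
  list(
    assessment = assessment,
    n_sites = nrow(per_site),
    sites_mean_within_50km = sum(per_site$within_max),
    sites_mean_within_10km = sum(per_site$within_min),
    n_human_sites = nrow(human),
    human_sites_majority_local_50km =
      sum(human[[sprintf("prop_%dkm", rmax)]] > 50, na.rm = TRUE)
  )
}
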