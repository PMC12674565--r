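#' Great-circle distance in kilometres
#'
#' Haversine distance on the WGS84 sphere between two sets of points given in
#' decimal degrees. Vectorised over both arguments (recycled pairwise).
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distances in km.
#' @export
gc_distance_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

#' Project lon/lat to local planar kilometre coordinates
#'
#' Lambert azimuthal equal-area projection centred on `center`. Geographic
#' degrees are anisotropic (a degree of longitude shrinks with latitude), so
#' any kilometre-scale planar logic (oblique coordinate features, spatial
#' blocking) runs on these coordinates rather than raw degrees.
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @param center Length-2 numeric `c(lon, lat)` of the projection centre;
#'   defaults to the centroid of the input points.
#' @return A two-column matrix (`x`, `y`) in km.
#' @export
project_local_km <- function(lon, lat, center = NULL) {
  if (is.null(center)) center <- c(mean(lon), mean(lat))
  R <- 6371
  lam <- (lon - center[1]) * pi / 180
  phi <- lat * pi / 180
  phi0 <- center[2] * pi / 180
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam)
  k <- sqrt(2 / denom)
  cbind(
    x = R * k * cos(phi) * sin(lam),
    y = R * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam))
  )
}

# Round half away from zero to `digits` decimals. base::round() rounds
# half-to-even; reported proportions follow the conventional half-up rule.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Plausible range for a bioavailable 87Sr/86Sr ratio; values outside are
# treated as data errors (or nodata sentinels) everywhere in the package.
SR_RATIO_MIN <- 0.700
SR_RATIO_MAX <- 0.760
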