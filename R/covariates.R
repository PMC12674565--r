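#' Registry of environmental covariates
#'
#' The ordered set of predictors the isoscape models draw on: mechanistic
#' bedrock-model ratio quantiles, lithological ages, climate, atmospheric
#' deposition, topography and soil properties. Raster stacks are matched to
#' this registry by name.
#'
#' @return Tibble with columns `name`, `description`, `units`.
#' @export
covariate_registry <- function() {
  tibble::tribble(
    ~name, ~description, ~units,
    "r.m1", "median bedrock-model 87Sr/86Sr", "ratio",
    "r.srsrq1", "1st-quartile bedrock-model 87Sr/86Sr", "ratio",
    "r.srsrq3", "3rd-quartile bedrock-model 87Sr/86Sr", "ratio",
    "r.meanage_geol", "mean lithological-unit age", "Myr",
    "r.minage_geol", "minimum lithological-unit age", "Myr",
    "r.maxage_geol", "maximum lithological-unit age", "Myr",
    "r.age", "terrane age", "Myr",
    "r.mat", "mean annual temperature", "deg C",
    "r.map", "mean annual precipitation", "mm/yr",
    "r.pet", "potential evapotranspiration", "mm/yr",
    "r.ai", "aridity index", "dimensionless",
    "r.salt", "sea-salt deposition", "g/m2/yr",
    "r.dust", "dust deposition", "g/m2/yr",
    "r.fire", "black-carbon deposition", "kg/m2/s",
    "r.foss", "fossil-fuel deposition", "kg/m2/s",
    "r.volc", "volcanic deposition", "kg/m2/s",
    "r.dist", "distance to coast", "km",
    "r.elevation", "elevation", "m",
    "r.bouguer", "Bouguer gravity anomaly", "mGal",
    "r.GUM", "unconsolidated-sediment class", "class",
    "r.cec", "cation exchange capacity", "mmol(c)/kg",
    "r.ph", "soil pH (H2O, x10)", "pH x10",
    "r.phkcl", "soil pH (KCl, x10)", "pH x10",
    "r.clay", "clay content", "g/kg",
    "r.ocs", "organic carbon stock", "t/ha",
    "r.bulk", "bulk density", "cg/cm3"
  )
}

#' Extract covariate values at sample sites
#'
#' Builds the sites x predictors matrix from a named raster stack. A site
#' falling on a nodata cell of some covariate receives the nearest valid
#' cell's value (great-circle distance between cell centres) provided that
#' cell lies within `max_fallback_km`; the substitution is flagged
#' `nearest-fallback`. A site outside every raster, or with no valid cell
#' within the search radius, is a hard error naming the site.
#'
#' @param stack Named list of `raster_grid`s (names must be unique; when a
#'   registry is enforced downstream, names should match it).
#' @param sites Tibble with `id` (or `site`), `longitude`, `latitude`, and
#'   optionally `sr_ratio` (carried through as the response).
#' @param max_fallback_km Radius of the nearest-valid-cell search, km.
#' @return A `covariate_matrix`: list with `data` (tibble: id + one column
#'   per covariate + `sr_ratio` if present), `provenance` (same shape,
#'   "direct" / "nearest-fallback"), and `fallback_km` (distances used, NA
#'   where direct).
#' @export
extract_at_points <- function(stack, sites, max_fallback_km = 50) {
  if (length(stack) == 0) stop("empty raster stack")
  if (is.null(names(stack)) || anyDuplicated(names(stack)))
    stop("stack must be a uniquely named list of rasters")
  ids <- if ("id" %in% names(sites)) sites$id
         else if ("site" %in% names(sites)) sites$site
         else as.character(seq_len(nrow(sites)))
  lon <- sites$longitude; lat <- sites$latitude

  vals <- matrix(NA_real_, nrow(sites), length(stack),
                 dimnames = list(NULL, names(stack)))
  prov <- matrix("direct", nrow(sites), length(stack),
                 dimnames = list(NULL, names(stack)))
  fdist <- matrix(NA_real_, nrow(sites), length(stack),
                  dimnames = list(NULL, names(stack)))

  for (nm in names(stack)) {
    g <- stack[[nm]]
    v <- rg_values(g)
    ctr <- rg_cell_centers(g)
    valid <- which(!is.na(v), arr.ind = TRUE)
    for (i in seq_len(nrow(sites))) {
      rc <- rg_cell_at(g, lon[i], lat[i])
      if (is.null(rc))
        stop("site '", ids[i], "' lies outside raster '", nm, "'")
      x <- v[rc[1], rc[2]]
      if (!is.na(x)) { vals[i, nm] <- x; next }
      if (nrow(valid) == 0)
        stop("raster '", nm, "' has no valid cells for site '", ids[i], "'")
      d <- gc_distance_km(ctr$x[valid[, 2]], ctr$y[valid[, 1]], lon[i], lat[i])
      j <- which.min(d)
      if (d[j] > max_fallback_km)
        stop("site '", ids[i], "': nearest valid cell of '", nm, "' is ",
             round(d[j], 1), " km away (> ", max_fallback_km, " km limit)")
      vals[i, nm] <- v[valid[j, 1], valid[j, 2]]
      prov[i, nm] <- "nearest-fallback"
      fdist[i, nm] <- d[j]
    }
  }
  data <- tibble::as_tibble(as.data.frame(vals))
  data <- dplyr::bind_cols(tibble::tibble(id = ids), data)
  if ("sr_ratio" %in% names(sites)) data$sr_ratio <- sites$sr_ratio
  structure(list(data = data, provenance = prov, fallback_km = fdist,
                 covariate_names = names(stack)),
            class = "covariate_matrix")
}

#' @export
print.covariate_matrix <- function(x, ...) {
  cat(sprintf("<covariate_matrix> %d sites x %d covariates (%d fallback fills)\n",
              nrow(x$data), length(x$covariate_names),
              sum(x$provenance == "nearest-fallback")))
  invisible(x)
}

# Numeric predictor matrix of a covariate_matrix (or pass-through matrix).
cm_predictors <- function(matrix, names = NULL) {
  if (inherits(matrix, "covariate_matrix")) {
    nms <- names %||% matrix$covariate_names
    as.matrix(matrix$data[nms])
  } else {
    m <- as.matrix(matrix)
    if (!is.null(names)) m[, names, drop = FALSE] else m
  }
}

cm_response <- function(matrix) {
  if (inherits(matrix, "covariate_matrix")) matrix$data$sr_ratio
  else attr(matrix, "response")
}

#' Drop strongly correlated predictors
#'
#' Iteratively removes one member of every predictor pair whose absolute
#' Pearson correlation exceeds `threshold`, until the maximum pairwise |R|
#' is at or below it. Of a violating pair, the member with the larger mean
#' absolute correlation against all remaining predictors is dropped; ties
#' break by column order. Zero-variance columns are dropped first with
#' their own diagnostic (their correlation is undefined).
#'
#' @param matrix A `covariate_matrix`, or a numeric matrix/data frame of
#'   predictors.
#' @param threshold Maximum tolerated pairwise |R|, in (0, 1).
#' @return List with `retained` (names), `dropped` (tibble: variable,
#'   partner, r, reason) and `max_abs_r` after pruning.
#' @export
prune_correlated <- function(matrix, threshold = 0.9) {
  stopifnot(threshold > 0, threshold < 1)
  x <- cm_predictors(matrix)
  if (ncol(x) < 2) stop("need at least 2 predictors to prune")
  dropped <- tibble::tibble(variable = character(), partner = character(),
                            r = numeric(), reason = character())
  sds <- apply(x, 2, stats::sd)
  for (nm in colnames(x)[sds == 0]) {
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      variable = nm, partner = NA_character_, r = NA_real_,
      reason = "zero variance"))
  }
  x <- x[, sds > 0, drop = FALSE]
  while (ncol(x) >= 2) {
    r <- abs(stats::cor(x))
    diag(r) <- 0
    if (max(r) <= threshold) break
    ij <- which(r == max(r), arr.ind = TRUE)[1, ]
    mean_abs <- rowMeans(r)  # mean |R| against the others (diag zeroed)
    cand <- c(ij[1], ij[2])
    drop_i <- cand[order(-mean_abs[cand], cand)][1]
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      variable = colnames(x)[drop_i],
      partner = colnames(x)[setdiff(cand, drop_i)[1]],
      r = max(r), reason = "correlated"))
    x <- x[, -drop_i, drop = FALSE]
  }
  max_r <- if (ncol(x) >= 2) {
    r <- abs(stats::cor(x)); diag(r) <- 0; max(r)
  } else 0
  list(retained = colnames(x), dropped = dropped, max_abs_r = max_r)
}
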