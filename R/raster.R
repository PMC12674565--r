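#' Georeferenced raster grid
#'
#' A minimal in-memory container for a single-band georeferenced raster:
#' a numeric matrix stored north-up (row 1 = northernmost row) plus an
#' origin/cell-size geotransform, a CRS string and a nodata sentinel.
#' All isoscape surfaces, uncertainty maps and environmental covariates in
#' this package are `raster_grid` objects.
#'
#' @param values Numeric matrix, `nrow` = rows (north to south), `ncol` =
#'   columns (west to east). `NA` entries are converted to `nodata`.
#' @param xmin,ymax Coordinates of the outer corner of the top-left cell
#'   (degrees for geographic CRS).
#' @param dx,dy Positive cell sizes in CRS units.
#' @param crs CRS identifier string (default WGS84).
#' @param nodata Sentinel marking missing cells. Must not collide with valid
#'   ratio values when the grid holds 87Sr/86Sr.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin, ymax, dx, dy = dx, crs = "EPSG:4326",
                        nodata = -9999) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (nrow(values) < 1 || ncol(values) < 1) stop("raster must have >= 1 cell")
  if (dx <= 0 || dy <= 0) stop("cell sizes must be positive")
  values[is.na(values)] <- nodata
  structure(
    list(values = values, xmin = xmin, ymax = ymax, dx = dx, dy = dy,
         crs = crs, nodata = nodata),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- rg_values(x)
  cat(sprintf(
    "<raster_grid> %d x %d cells, dx=%.6g dy=%.6g, origin (%.6g, %.6g), %s\n",
    nrow(x$values), ncol(x$values), x$dx, x$dy, x$xmin, x$ymax, x$crs))
  cat(sprintf("  valid cells: %d/%d, range [%.6g, %.6g]\n",
              sum(!is.na(v)), length(v),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' Raster values with nodata masked to NA
#' @param grid A `raster_grid`.
#' @return Numeric matrix with nodata cells as `NA`.
#' @export
rg_values <- function(grid) {
  v <- grid$values
  v[v == grid$nodata] <- NA_real_
  v
}

#' Cell-centre coordinates of a raster grid
#'
#' @param grid A `raster_grid`.
#' @return List with vectors `x` (west to east, length ncol) and `y`
#'   (north to south, length nrow) of cell-centre coordinates.
#' @export
rg_cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  list(
    x = grid$xmin + (seq_len(nc) - 0.5) * grid$dx,
    y = grid$ymax - (seq_len(nr) - 0.5) * grid$dy
  )
}

#' Locate the cell containing a point
#'
#' @param grid A `raster_grid`.
#' @param x,y Point coordinates in the grid CRS.
#' @return Integer vector `c(row, col)`, or `NULL` if outside the extent.
#' @export
rg_cell_at <- function(grid, x, y) {
  col <- floor((x - grid$xmin) / grid$dx) + 1
  row <- floor((grid$ymax - y) / grid$dy) + 1
  if (col < 1 || col > ncol(grid$values) || row < 1 || row > nrow(grid$values))
    return(NULL)
  c(row = as.integer(row), col = as.integer(col))
}

#' Do two grids share the same geometry?
#' @param a,b `raster_grid` objects.
#' @return Logical.
#' @export
rg_aligned <- function(a, b) {
  isTRUE(all.equal(dim(a$values), dim(b$values))) &&
    isTRUE(all.equal(c(a$xmin, a$ymax, a$dx, a$dy), c(b$xmin, b$ymax, b$dx, b$dy))) &&
    identical(a$crs, b$crs)
}

#' Read a raster from an ESRI ASCII grid
#'
#' Reads the plain-text `.asc` interchange format (header of
#' ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value followed by rows
#' north to south). The CRS is taken from a `<path>.prj` sidecar if present;
#' otherwise `crs` must be supplied explicitly.
#'
#' @param path Path to the `.asc` file.
#' @param crs CRS override; required when no `.prj` sidecar exists.
#' @return A `raster_grid`.
#' @export
read_raster <- function(path, crs = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, n = 6)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing header keys): ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  nskip <- if (!is.null(hdr$nodata_value)) 6 else 5
  vals <- scan(path, skip = nskip, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("cell count mismatch in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  prj <- paste0(path, ".prj")
  if (is.null(crs)) {
    if (file.exists(prj)) {
      crs <- trimws(readLines(prj, n = 1))
    } else {
      stop("no CRS sidecar for ", path,
           "; pass crs = \"EPSG:...\" explicitly to override")
    }
  }
  raster_grid(m,
              xmin = hdr$xllcorner,
              ymax = hdr$yllcorner + hdr$nrows * hdr$cellsize,
              dx = hdr$cellsize, dy = hdr$cellsize,
              crs = crs, nodata = nodata)
}

#' Write a raster to an ESRI ASCII grid
#'
#' Writes `grid` as a plain-text `.asc` file plus a `<path>.prj` sidecar
#' holding the CRS string. The format carries a single square cell size, so
#' `dx` must equal `dy`.
#'
#' @param grid A `raster_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  if (!isTRUE(all.equal(grid$dx, grid$dy)))
    stop("ESRI ASCII grids require square cells (dx == dy)")
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.12g", grid$xmin),
    sprintf("yllcorner %.12g", grid$ymax - nr * grid$dy),
    sprintf("cellsize %.12g", grid$dx),
    sprintf("NODATA_value %.12g", grid$nodata)
  ), con)
  for (i in seq_len(nr)) {
    writeLines(paste(formatC(grid$values[i, ], format = "g", digits = 15),
                     collapse = " "), con)
  }
  writeLines(grid$crs, paste0(path, ".prj"))
  invisible(path)
}

#' Extract raster values at point locations (no fallback)
#'
#' Nodata cells and out-of-extent points yield `NA`. See
#' [extract_at_points()] for the nearest-valid-cell fallback used to build
#' covariate matrices.
#'
#' @param grid A `raster_grid`.
#' @param lon,lat Point coordinates in the grid CRS.
#' @return Numeric vector of values (`NA` where missing).
#' @export
rg_extract <- function(grid, lon, lat) {
  v <- rg_values(grid)
  vapply(seq_along(lon), function(i) {
    rc <- rg_cell_at(grid, lon[i], lat[i])
    if (is.null(rc)) NA_real_ else v[rc[1], rc[2]]
  }, numeric(1))
}
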