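#' @importFrom rlang .data
NULL

MATERIALS <- c("plant", "soil", "animal", "human")

# Canonical column sets per schema. "sm1" is the bioavailable-database
# layout (one measurement per row, georeferenced modern samples); "sm2" is
# the archaeological/modern site compilation (adds site, period, source and
# a coordinate-provenance flag); "synthetic" extends sm1 with the generating
# truth for parameter-recovery tests.
SCHEMA_COLS <- list(
  sm1 = c("id", "longitude", "latitude", "material", "sr_ratio", "sr_2sigma"),
  sm2 = c("site", "longitude", "latitude", "material", "period",
          "sr_ratio", "source", "coord_provenance"),
  synthetic = c("id", "longitude", "latitude", "material", "sr_ratio",
                "sr_2sigma", "true_ratio", "cell_row", "cell_col")
)

#' Read a 87Sr/86Sr sample table
#'
#' Reads a CSV sample database in one of three layouts and returns typed,
#' validated records. Rows violating hard invariants (coordinates off the
#' globe, ratios outside the plausible (0.700, 0.760) window, negative
#' uncertainties, unknown material) are rejected and reported row-by-row;
#' the parse is total — every input row is either returned or accounted for
#' in the rejection report.
#'
#' @param path CSV file path.
#' @param schema One of `"sm1"`, `"sm2"`, `"synthetic"` (see Details).
#' @return For `sm1`/`synthetic`: a tibble of sample records with attribute
#'   `rejected` (tibble of row index + reason). For `sm2`: a `site_table`
#'   (see [site_table()]).
#' @details Material vocabulary (`plant`, `soil`, `animal`, `human`) is
#'   normalised case-insensitively. A missing mandatory column is a schema
#'   error naming the column.
#' @export
read_sample_table <- function(path, schema = c("sm1", "sm2", "synthetic")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("sample table not found: ", path)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  cols <- SCHEMA_COLS[[schema]]
  optional <- c("sr_2sigma", "period", "source", "coord_provenance")
  missing_cols <- setdiff(setdiff(cols, optional), names(raw))
  if (length(missing_cols) > 0)
    stop("schema '", schema, "' requires missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (oc in intersect(optional, cols))
    if (!oc %in% names(raw)) raw[[oc]] <- NA_character_

  out <- raw[cols]
  numcols <- intersect(c("longitude", "latitude", "sr_ratio", "sr_2sigma",
                         "true_ratio", "cell_row", "cell_col"), cols)
  for (nc in numcols) out[[nc]] <- suppressWarnings(as.numeric(out[[nc]]))
  out$material <- tolower(trimws(out$material))

  reasons <- rep(NA_character_, nrow(out))
  flag <- function(bad, why) {
    bad <- which(bad & is.na(reasons))
    reasons[bad] <<- why
  }
  flag(is.na(out$longitude) | is.na(out$latitude), "unparseable coordinates")
  flag(abs(out$longitude) > 180 | abs(out$latitude) > 90,
       "coordinates outside valid range")
  flag(!out$material %in% MATERIALS,
       paste0("material not one of {", paste(MATERIALS, collapse = ", "), "}"))
  flag(is.na(out$sr_ratio), "unparseable sr_ratio")
  flag(out$sr_ratio <= SR_RATIO_MIN | out$sr_ratio >= SR_RATIO_MAX,
       "sr_ratio outside plausible (0.700, 0.760) range")
  if ("sr_2sigma" %in% cols)
    flag(!is.na(out$sr_2sigma) & out$sr_2sigma < 0, "negative sr_2sigma")

  rejected <- tibble::tibble(row = which(!is.na(reasons)),
                             reason = reasons[!is.na(reasons)])
  kept <- out[is.na(reasons), , drop = FALSE]
  kept <- tibble::as_tibble(kept)
  attr(kept, "rejected") <- rejected
  if (schema == "sm2") return(site_table(kept, rejected = rejected))
  kept
}

#' Write a sample table to CSV
#'
#' @param samples Tibble of sample records (sm1/synthetic layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  readr::write_csv(samples, path)
  invisible(path)
}

#' Group per-sample records into a site table
#'
#' Archaeological compilations pool measurements from several source studies
#' per site; downstream assessment works site-by-site. A `site_table` keeps
#' the per-sample rows plus a per-site summary (one representative
#' coordinate, sample count, coordinate-provenance flag). Sites whose source
#' published only a summary value (a single row flagged `summary-only` via
#' `coord_provenance`) are carried with `summary_only = TRUE`.
#'
#' @param samples Tibble with sm2-layout columns.
#' @param rejected Optional rejection report to attach.
#' @return A `site_table`: list of `samples` (tibble) and `sites` (tibble).
#' @export
site_table <- function(samples, rejected = NULL) {
  stopifnot(all(c("site", "longitude", "latitude", "material", "sr_ratio")
                %in% names(samples)))
  if (nrow(samples) > 0 && any(is.na(samples$site) | samples$site == ""))
    stop("every sample in a site table needs a site label")
  sites <- samples |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(
      longitude = mean(.data$longitude),
      latitude = mean(.data$latitude),
      n_samples = dplyr::n(),
      coord_provenance = {
        cp <- unique(stats::na.omit(.data$coord_provenance))
        if (length(cp) == 0) "exact" else paste(cp, collapse = ";")
      },
      summary_only = all(.data$coord_provenance %in% "summary-only"),
      .groups = "drop"
    )
  structure(list(samples = tibble::as_tibble(samples), sites = sites,
                 rejected = rejected %||%
                   tibble::tibble(row = integer(), reason = character())),
            class = "site_table")
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf("<site_table> %d sites, %d samples (%d rows rejected on read)\n",
              nrow(x$sites), nrow(x$samples), nrow(x$rejected)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
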