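#' Administrative regions and their activity data
#'
#' An AdminSet is a data.frame with one row per administrative unit
#' (counties, plus optional province parent rows), carrying the activity
#' data the budget equations consume:
#'
#' \itemize{
#'   \item `region_id`, `parent_id` (`NA` for top level), `level`
#'     ("province" or "county"), `raster_code` (integer code of the unit in
#'     the region raster; `NA` for units not rasterized),
#'   \item `pop_urban`, `pop_rural` (persons), `gdp` (currency units/yr),
#'   \item `fertilizer_cropland`, `fertilizer_forest`,
#'     `fertilizer_grassland` (kg N/yr),
#'   \item `livestock_<category>` (head), `area_<crop>` (planting area, ha),
#'   \item `lu_<class>` (land-use area, ha; class names with `-` mapped to
#'     `_`, e.g. `lu_built_up`).
#' }
#'
#' @name admin_set
NULL

lu_col <- function(class) paste0("lu_", gsub("-", "_", class))

prefixed_cols <- function(region, prefix) {
  cols <- grep(paste0("^", prefix), names(region), value = TRUE)
  vals <- as.numeric(region[1, cols])
  stats::setNames(vals, sub(paste0("^", prefix), "", cols))
}

#' Extract per-category activity vectors from a region row
#'
#' @param region One-row data.frame from an AdminSet.
#' @return Named numeric vector: `region_livestock` head counts per animal
#'   category, `region_planting` planting area (ha) per crop,
#'   `region_landuse_areas` area (ha) per land-use class.
#' @export
region_livestock <- function(region) prefixed_cols(region, "livestock_")

#' @rdname region_livestock
#' @export
region_planting <- function(region) prefixed_cols(region, "area_")

#' @rdname region_livestock
#' @export
region_landuse_areas <- function(region) {
  x <- prefixed_cols(region, "lu_")
  names(x) <- sub("^built_up$", "built-up", names(x))
  x
}

#' Validate an AdminSet
#'
#' Checks column presence, uniqueness of `region_id`, non-negativity of all
#' quantities, and — when province parent rows are present — that child
#' land-use areas sum to the parent's within `tol` relative.
#'
#' @param regions AdminSet data.frame.
#' @param tol Relative tolerance for hierarchy closure (default 1e-9).
#' @return The AdminSet, invisibly, or an error.
#' @export
validate_admin_set <- function(regions, tol = 1e-9) {
  need <- c("region_id", "parent_id", "level", "pop_urban", "pop_rural",
            "gdp", "fertilizer_cropland")
  miss <- setdiff(need, names(regions))
  if (length(miss))
    stop("AdminSet missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(regions$region_id))
    stop("region_id values must be unique", call. = FALSE)
  num_cols <- names(regions)[vapply(regions, is.numeric, logical(1))]
  for (cl in setdiff(num_cols, "raster_code")) {
    x <- regions[[cl]]
    if (any(!is.finite(x)) || any(x < 0))
      stop("negative or non-finite values in AdminSet column '", cl, "'",
           call. = FALSE)
  }
  parents <- regions[regions$level == "province", , drop = FALSE]
  if (nrow(parents)) {
    kids <- regions[regions$level == "county", , drop = FALSE]
    lu_cols <- grep("^lu_", names(regions), value = TRUE)
    for (p in parents$region_id) {
      sub <- kids[kids$parent_id == p, , drop = FALSE]
      if (!nrow(sub)) next
      for (cl in lu_cols) {
        a <- sum(sub[[cl]]); b <- parents[[cl]][parents$region_id == p]
        if (abs(a - b) > tol * max(1, abs(b)))
          stop("land-use areas of counties in ", p,
               " do not close to the province total (", cl, ")",
               call. = FALSE)
      }
    }
  }
  invisible(regions)
}

#' County-level rows of an AdminSet
#' @param regions AdminSet.
#' @return Data.frame of county rows.
#' @export
admin_counties <- function(regions) {
  regions[regions$level == "county", , drop = FALSE]
}

#' Read / write an AdminSet as CSV
#'
#' @param regions AdminSet data.frame.
#' @param path CSV path.
#' @return `read_admin_set` returns a validated AdminSet; the writer returns
#'   `path` invisibly.
#' @export
write_admin_set <- function(regions, path) {
  validate_admin_set(regions)
  out <- regions
  for (cl in names(out))
    if (is.numeric(out[[cl]]) && cl != "raster_code")
      out[[cl]] <- sprintf("%.17g", out[[cl]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_admin_set
#' @export
read_admin_set <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(region_id = "character",
                                      parent_id = "character"))
  for (cl in setdiff(names(x), c("region_id", "parent_id", "level")))
    x[[cl]] <- if (cl == "raster_code") as.integer(x[[cl]]) else
      as.numeric(x[[cl]])
  validate_admin_set(x)
  x
}

#' Write rectangular region footprints as GeoJSON
#'
#' Serializes axis-aligned region rectangles (as produced by the synthetic
#' generator) to a GeoJSON FeatureCollection of Polygons with `region_id`
#' and `raster_code` properties.
#'
#' @param rects Data.frame with columns region_id, raster_code, xmin, xmax,
#'   ymin, ymax (map units).
#' @param path Output path (.geojson).
#' @return `path`, invisibly.
#' @export
write_region_geojson <- function(rects, path) {
  feats <- lapply(seq_len(nrow(rects)), function(i) {
    r <- rects[i, ]
    ring <- list(c(r$xmin, r$ymin), c(r$xmax, r$ymin), c(r$xmax, r$ymax),
                 c(r$xmin, r$ymax), c(r$xmin, r$ymin))
    list(type = "Feature",
         properties = list(region_id = r$region_id,
                           raster_code = r$raster_code),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read region rectangles back from GeoJSON
#' @param path GeoJSON path written by [write_region_geojson()].
#' @return Data.frame with region_id, raster_code and bounding coordinates.
#' @export
read_region_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  rows <- lapply(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    data.frame(region_id = f$properties$region_id,
               raster_code = as.integer(f$properties$raster_code),
               xmin = min(xs), xmax = max(xs),
               ymin = min(ys), ymax = max(ys),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
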