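#' Single-variable raster on the analysis grid
#'
#' A `grid_map` wraps a numeric matrix with an affine georeference
#' (lower-left corner, square cell size) and a nodata sentinel. Row 1 of
#' the matrix is the northernmost row; pixel extents are half-open and a
#' cell belongs to the region containing its center. Flux layers hold
#' whole-cell totals (kg N/cell); class/region layers hold integer codes.
#'
#' @param values Numeric matrix (row 1 = north).
#' @param xll,yll Coordinates of the lower-left corner of the grid (m).
#' @param cellsize Cell edge length (m); cells are square.
#' @param nodata Nodata sentinel stored on disk; in memory nodata cells are
#'   `NA` and `nodata` is only the serialization value.
#' @param crs Free-text coordinate reference identifier.
#' @return An object of class `grid_map`.
#' @export
grid_map <- function(values, xll = 0, yll = 0, cellsize = 1000,
                     nodata = -9999, crs = "local-equal-area-metre") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(is.infinite(values)))
    stop("grid values must be finite or NA", call. = FALSE)
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata, crs = crs),
            class = "grid_map")
}

#' @export
print.grid_map <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid_map %d x %d, cellsize %g m, origin (%g, %g)>\n",
              nrow(v), ncol(v), x$cellsize, x$xll, x$yll))
  cat(sprintf("  non-NA cells: %d, total: %g\n",
              sum(!is.na(v)), sum(v, na.rm = TRUE)))
  invisible(x)
}

#' Test that two grids share shape and georeference
#' @param a,b `grid_map` objects.
#' @return Logical scalar.
#' @export
grid_compatible <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xll, a$yll, a$cellsize),
                     c(b$xll, b$yll, b$cellsize)))
}

stop_if_incompatible <- function(a, b, what = "grids") {
  if (!grid_compatible(a, b))
    stop(what, " have mismatched shape or georeference", call. = FALSE)
  invisible(TRUE)
}

#' Total mass of a flux grid
#' @param map `grid_map` in kg N/cell.
#' @return Sum over non-NA cells (kg N).
#' @export
grid_total <- function(map) sum(map$values, na.rm = TRUE)

#' Cell area in hectares implied by the grid's cell size
#' @param map `grid_map`.
#' @return Scalar area of one cell in ha (cellsize in metres).
#' @export
cell_area_ha <- function(map) (map$cellsize^2) / 1e4

#' Zonal sums of a value grid over an integer zone grid
#'
#' @param map `grid_map` of values (kg N/cell); NA cells contribute nothing.
#' @param zones `grid_map` of integer zone codes (NA = outside all zones).
#' @return Named numeric vector: zone code (as character) -> sum.
#' @export
zonal_sum <- function(map, zones) {
  stop_if_incompatible(map, zones, "value and zone grids")
  v <- as.vector(map$values)
  z <- as.vector(zones$values)
  keep <- !is.na(v) & !is.na(z)
  if (!any(keep)) return(stats::setNames(numeric(0), character(0)))
  out <- tapply(v[keep], z[keep], sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Convert a kg-per-cell map to kg per hectare
#'
#' @param map_kg `grid_map` in kg N/cell.
#' @param area_ha Cell area in hectares; defaults to the area implied by
#'   the grid's cell size. Must be positive.
#' @return `grid_map` in kg N/ha; nodata (NA) cells preserved.
#' @export
per_hectare <- function(map_kg, area_ha = cell_area_ha(map_kg)) {
  if (!is.numeric(area_ha) || length(area_ha) != 1L ||
      !is.finite(area_ha) || area_ha <= 0)
    stop("cell area must be a single positive number", call. = FALSE)
  out <- map_kg
  out$values <- map_kg$values / area_ha
  out
}

#' Cell-wise sum of a list of flux maps
#'
#' Layers are summed treating NA as 0 wherever at least one layer has data;
#' cells that are NA in every layer stay NA. Total mass of the result equals
#' the sum of the layer masses.
#'
#' @param maps Non-empty list of compatible `grid_map`s (kg N/cell).
#' @return Combined `grid_map`.
#' @export
combine_maps <- function(maps) {
  if (!is.list(maps) || length(maps) == 0L)
    stop("combine_maps() needs a non-empty list of grids", call. = FALSE)
  base <- maps[[1]]
  acc <- matrix(0, nrow(base$values), ncol(base$values))
  any_data <- matrix(FALSE, nrow(base$values), ncol(base$values))
  for (m in maps) {
    stop_if_incompatible(base, m)
    has <- !is.na(m$values)
    acc[has] <- acc[has] + m$values[has]
    any_data <- any_data | has
  }
  acc[!any_data] <- NA_real_
  out <- base
  out$values <- acc
  out
}

#' Read and write grids as ESRI ASCII grid (.asc)
#'
#' Plain-text single-band raster: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of values,
#' north row first. Values are written with up to 17 significant digits so
#' doubles round-trip bit-exactly through the decimal representation.
#'
#' @param map `grid_map` to write.
#' @param path File path (.asc).
#' @return `write_asc` returns `path` invisibly; `read_asc` a `grid_map`.
#' @export
write_asc <- function(map, path) {
  v <- map$values
  v[is.na(v)] <- map$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", map$xll),
    sprintf("yllcorner %.10g", map$yll),
    sprintf("cellsize %.10g", map$cellsize),
    sprintf("NODATA_value %.10g", map$nodata)
  ), con)
  writeLines(apply(v, 1L, function(r) paste(sprintf("%.17g", r),
                                            collapse = " ")), con)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr$nrows)
    stop("ASCII grid row count does not match header", call. = FALSE)
  vals <- vapply(body, function(r) as.numeric(strsplit(trimws(r),
                                                       "\\s+")[[1]]),
                 numeric(hdr$ncols), USE.NAMES = FALSE)
  v <- t(vals)  # vapply gives cols x rows
  if (!is.matrix(v)) v <- matrix(v, nrow = hdr$nrows)
  v[v == hdr$nodata_value] <- NA_real_
  grid_map(v, xll = hdr$xllcorner, yll = hdr$yllcorner,
           cellsize = hdr$cellsize, nodata = hdr$nodata_value)
}
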