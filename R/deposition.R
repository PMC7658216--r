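#' Daily trace-gas column series on a coarse grid
#'
#' Holds ordered daily 2-D column fields (e.g. NO2 or NH3 vertical columns,
#' molecules/cm2 or an arbitrary index) for one month on a coarse grid,
#' with a per-day validity mask (satellite coverage). All days share the
#' grid; masked cells are excluded from compositing.
#'
#' @param species "NO2" or "NH3".
#' @param fields 3-D array day x row x col of column values.
#' @param valid Logical array of the same shape; TRUE = observed.
#' @param xll,yll,cellsize,crs Georeference of the coarse grid.
#' @return A `column_series` object.
#' @export
column_series <- function(species, fields, valid = NULL, xll = 0, yll = 0,
                          cellsize = 8000, crs = "local-equal-area-metre") {
  species <- match.arg(species, c("NO2", "NH3"))
  if (length(dim(fields)) != 3L)
    stop("fields must be a day x row x col array", call. = FALSE)
  if (is.null(valid)) valid <- array(TRUE, dim(fields))
  if (!identical(dim(valid), dim(fields)))
    stop("valid mask must match fields in shape", call. = FALSE)
  structure(list(species = species, fields = fields,
                 valid = as.logical(valid) |> array(dim(fields)),
                 xll = xll, yll = yll, cellsize = cellsize, crs = crs),
            class = "column_series")
}

#' Monthly composite of a daily column series (arithmetic mean)
#'
#' Per-cell arithmetic mean over the days with a valid observation; cells
#' observed on no day become nodata.
#'
#' @param series `column_series`.
#' @return `grid_map` of monthly-mean columns on the coarse grid.
#' @export
monthly_mean <- function(series) {
  if (!inherits(series, "column_series") || dim(series$fields)[1] == 0L)
    stop("empty column series", call. = FALSE)
  f <- series$fields
  f[!series$valid] <- NA_real_
  m <- apply(f, c(2, 3), function(x) {
    x <- x[!is.na(x)]
    if (length(x)) mean(x) else NA_real_
  })
  grid_map(m, xll = series$xll, yll = series$yll,
           cellsize = series$cellsize, crs = series$crs)
}

#' Combined deposition weighting index from NO2 and NH3 columns
#'
#' Each monthly column map is normalized by its maximum (so the index is
#' invariant to a common rescaling of either input), then combined as a
#' weighted sum and clamped at zero. Cells missing one species use the
#' other alone; cells missing both are nodata. The index is a spatial
#' weight only — deposition magnitudes come from configured class totals.
#'
#' @param no2_monthly,nh3_monthly Monthly `grid_map`s on a common grid.
#' @param weights Numeric pair (no2, nh3), non-negative, not both zero.
#' @return `grid_map` index (unitless, >= 0).
#' @export
deposition_index <- function(no2_monthly, nh3_monthly,
                             weights = c(0.5, 0.5)) {
  stop_if_incompatible(no2_monthly, nh3_monthly, "column grids")
  if (length(weights) != 2L || any(weights < 0) || sum(weights) == 0)
    stop("weights must be two non-negative numbers, not both zero",
         call. = FALSE)
  norm <- function(m) {
    mx <- suppressWarnings(max(m$values, na.rm = TRUE))
    if (!is.finite(mx) || mx <= 0) return(m$values * 0)
    m$values / mx
  }
  a <- norm(no2_monthly) * weights[1]
  b <- norm(nh3_monthly) * weights[2]
  both_na <- is.na(a) & is.na(b)
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  v <- pmax(a + b, 0)
  v[both_na] <- NA_real_
  out <- no2_monthly
  out$values <- v
  out
}

#' Resample a coarse grid onto a fine grid by nearest-cell lookup
#'
#' Each fine cell takes the value of the coarse cell containing its
#' center (block-constant transfer), which keeps subsequent class-wise
#' renormalization exactly mass-conserving.
#'
#' @param coarse `grid_map` on the coarse grid.
#' @param fine_template `grid_map` supplying the fine geometry.
#' @return `grid_map` on the fine grid.
#' @export
resample_nearest <- function(coarse, fine_template) {
  fv <- fine_template$values
  nr <- nrow(fv); nc <- ncol(fv)
  # centers of fine cells (row 1 = north)
  xc <- fine_template$xll + (seq_len(nc) - 0.5) * fine_template$cellsize
  yc <- fine_template$yll + (nr - seq_len(nr) + 0.5) * fine_template$cellsize
  ci <- pmin(pmax(floor((xc - coarse$xll) / coarse$cellsize) + 1L, 1L),
             ncol(coarse$values))
  cr_top <- coarse$yll + nrow(coarse$values) * coarse$cellsize
  ri <- pmin(pmax(floor((cr_top - yc) / coarse$cellsize) + 1L, 1L),
             nrow(coarse$values))
  out <- fine_template
  out$values <- coarse$values[cbind(rep(ri, times = nc),
                                    rep(ci, each = nr))] |>
    matrix(nrow = nr, ncol = nc)
  out
}

#' Allocate national deposition totals over land-use classes by column index
#'
#' The coarse deposition index is transferred to the fine analysis grid by
#' nearest-cell lookup; each land-use class's configured national
#' deposition total is then spread over that class's cells proportionally
#' to the index (uniformly if the class's index sum is zero). Per-class
#' re-aggregation recovers the configured totals exactly.
#'
#' @param index `grid_map` deposition index on the coarse grid (or already
#'   on the fine grid).
#' @param landuse `grid_map` of land-use class codes on the fine grid.
#' @param national_totals Named vector class -> kg N/yr.
#' @param region_raster Optional `grid_map` of county codes; when given,
#'   regional deposition rows (zonal sums per county per class) are
#'   returned alongside the national rows.
#' @param regions Optional AdminSet to translate raster codes back to
#'   region ids for the regional rows.
#' @return List: `table` (flux table of "N deposition" records),
#'   `maps` (named list of per-class kg/cell `grid_map`s),
#'   `map` (combined deposition `grid_map`).
#' @export
deposition_by_landuse <- function(index, landuse, national_totals,
                                  region_raster = NULL, regions = NULL) {
  fine_index <- if (grid_compatible(index, landuse)) index else
    resample_nearest(index, landuse)
  maps <- list()
  recs <- list()
  for (class in names(national_totals)) {
    total <- national_totals[[class]]
    mask <- landuse_mask(landuse, class)
    if (total > 0 && !any(mask$values > 0, na.rm = TRUE))
      stop("deposition total configured for class '", class,
           "' but the land-use grid has no such cells", call. = FALSE)
    m <- allocate(c("1" = total), all_one_regions(landuse), fine_index, mask)
    maps[[class]] <- m
    recs[[class]] <- flux_record(class, "N deposition", total, "national")
  }
  tab <- flux_table(recs)
  if (!is.null(region_raster)) {
    counties <- admin_counties(regions)
    reg_rows <- list()
    for (class in names(maps)) {
      zs <- zonal_sum(maps[[class]], region_raster)
      ids <- counties$region_id[match(as.numeric(names(zs)),
                                      counties$raster_code)]
      for (i in seq_along(zs))
        reg_rows[[length(reg_rows) + 1L]] <-
          flux_record(class, "N deposition", zs[[i]], ids[i])
    }
    tab <- flux_table(c(list(tab), reg_rows))
  }
  list(table = tab, maps = maps, map = combine_maps(maps))
}

# single-region raster covering the whole domain of a template grid
all_one_regions <- function(template) {
  out <- template
  v <- matrix(1, nrow(template$values), ncol(template$values))
  v[is.na(template$values)] <- NA_real_
  out$values <- v
  out
}

#' Write / read a daily column series as a plain-text stack
#'
#' Serialization is a JSON header (species, grid geometry, day count) plus
#' a long-format CSV (day, row, col, value, valid); compact, diff-able and
#' exact (17 significant digits).
#'
#' @param series `column_series`.
#' @param path_base Path without extension; writes `<base>.json` and
#'   `<base>.csv`.
#' @return The writer returns `path_base` invisibly; the reader a
#'   `column_series`.
#' @export
write_column_series <- function(series, path_base) {
  d <- dim(series$fields)
  hdr <- list(species = series$species, days = d[1], nrows = d[2],
              ncols = d[3], xll = series$xll, yll = series$yll,
              cellsize = series$cellsize, crs = series$crs)
  jsonlite::write_json(hdr, paste0(path_base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  idx <- which(!is.na(series$fields), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
  df <- data.frame(day = idx[, 1], row = idx[, 2], col = idx[, 3],
                   value = sprintf("%.17g", series$fields[idx]),
                   valid = as.integer(series$valid[idx]))
  utils::write.csv(df, paste0(path_base, ".csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path_base)
}

#' @rdname write_column_series
#' @export
read_column_series <- function(path_base) {
  hdr <- jsonlite::read_json(paste0(path_base, ".json"))
  df <- utils::read.csv(paste0(path_base, ".csv"))
  fields <- array(NA_real_, c(hdr$days, hdr$nrows, hdr$ncols))
  valid <- array(FALSE, c(hdr$days, hdr$nrows, hdr$ncols))
  ix <- cbind(df$day, df$row, df$col)
  fields[ix] <- as.numeric(df$value)
  valid[ix] <- df$valid == 1L
  column_series(hdr$species, fields, valid, xll = hdr$xll, yll = hdr$yll,
                cellsize = hdr$cellsize, crs = hdr$crs)
}
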