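#' Runoff export from a source subsystem to surface water
#'
#' Cell-wise coefficient x source map, so the runoff map inherits the
#' source's spatial distribution (cropland runoff looks like cropland
#' input, livestock runoff like manure, etc.); the national record is
#' coefficient x source mass.
#'
#' @param source_map `grid_map` of the source flux (kg N/cell).
#' @param coeff Runoff coefficient, fraction in [0, 1].
#' @param item Water-budget item name (e.g. "cropland runoff").
#' @return List: `map` (`grid_map` kg N/cell), `record` (one-row flux
#'   table, region "national").
#' @export
runoff_flux <- function(source_map, coeff, item) {
  if (!is.numeric(coeff) || length(coeff) != 1L || !is.finite(coeff) ||
      coeff < 0 || coeff > 1)
    stop("runoff coefficient must be a fraction in [0,1]", call. = FALSE)
  out <- source_map
  out$values <- source_map$values * coeff
  list(map = out,
       record = flux_record("water", item, coeff * grid_total(source_map)))
}

#' Wastewater discharges to surface water
#'
#' Three socioeconomically driven inputs: human wastewater (per-capita
#' coefficient x total population, mapped by the population surface),
#' industrial wastewater (intensity x GDP, mapped by the GDP surface) and
#' WTP effluent (per-capita coefficient x urban population, mapped by the
#' urban-population surface). Each map conserves its national magnitude.
#'
#' @param regions AdminSet.
#' @param coeffs Coefficient library.
#' @param proxies Named list of `grid_map`s: `population`,
#'   `urban_population`, `gdp`.
#' @param region_raster `grid_map` of county raster codes.
#' @return Named list (item -> list(map, record)) for the three items.
#' @export
wastewater_fluxes <- function(regions, coeffs, proxies, region_raster) {
  need <- c("population", "urban_population", "gdp")
  miss <- setdiff(need, names(proxies))
  if (length(miss))
    stop("missing proxy grid(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  counties <- admin_counties(regions)
  per_region <- function(vals)
    stats::setNames(vals, as.character(counties$raster_code))
  spec <- list(
    "human wastewater discharged" = list(
      mag = coeffs$wastewater_per_capita *
        (counties$pop_urban + counties$pop_rural),
      proxy = proxies$population),
    "industrial wastewater" = list(
      mag = coeffs$industrial_n_per_gdp * counties$gdp,
      proxy = proxies$gdp),
    "WTP effluent" = list(
      mag = coeffs$wtp_effluent_per_capita * counties$pop_urban,
      proxy = proxies$urban_population)
  )
  lapply(stats::setNames(names(spec), names(spec)), function(item) {
    s <- spec[[item]]
    list(map = allocate(per_region(s$mag), region_raster, s$proxy),
         record = flux_record("water", item, sum(s$mag)))
  })
}

#' Zonal surface-water budget per watershed
#'
#' Sums each water-input map over the basins of a watershed partition.
#' Cells outside every basin are booked under basin_id "unassigned", so
#' basins + unassigned always reproduce the national total exactly.
#'
#' @param water_maps Named list (item -> `grid_map` kg N/cell).
#' @param basin_raster `grid_map` of integer basin codes (NA = unassigned).
#' @param basin_ids Optional named translation: raster code (character) ->
#'   basin id.
#' @return Data.frame (basin_id, item, kgN_per_yr).
#' @export
watershed_totals <- function(water_maps, basin_raster, basin_ids = NULL) {
  if (!length(water_maps))
    stop("no water-input maps supplied", call. = FALSE)
  if (all(is.na(basin_raster$values)))
    stop("no basins defined in the basin raster", call. = FALSE)
  rows <- list()
  for (item in names(water_maps)) {
    m <- water_maps[[item]]
    zs <- zonal_sum(m, basin_raster)
    unassigned <- grid_total(m) - sum(zs)
    ids <- if (is.null(basin_ids)) names(zs) else
      unname(basin_ids[names(zs)])
    rows[[item]] <- rbind(
      data.frame(basin_id = ids, item = item, kgN_per_yr = unname(zs),
                 stringsAsFactors = FALSE),
      data.frame(basin_id = "unassigned", item = item,
                 kgN_per_yr = unassigned, stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a basin table as CSV
#' @param basin_table Data.frame from [watershed_totals()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_basin_table <- function(basin_table, path) {
  out <- basin_table
  out$kgN_per_yr <- sprintf("%.17g", out$kgN_per_yr)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
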