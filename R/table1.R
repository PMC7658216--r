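#' Packaged national N-input summary table (2017, Tg N)
#'
#' The published national summary of reactive-nitrogen inputs to the six
#' land-use types for China in 2017, as shipped with the package: 24 rows
#' of (land use, item, Tg N/yr). This is reference data, not a computation;
#' it serves as a fixture for the report formatter and as the default
#' source of per-class deposition totals.
#'
#' @param units "Tg" (as published, default) or "kg" (x 1e9, the package's
#'   internal unit, in a `kgN_per_yr` column).
#' @return Flux table with 24 national rows; in "Tg" mode the magnitude
#'   column is `Tg_per_yr`.
#' @export
table1_fixture <- function(units = c("Tg", "kg")) {
  units <- match.arg(units)
  tg <- c(
    # cropland
    28.9, 5.9, 0.7, 5.3, 1.6, 4.6, 2.4,
    # forest
    2.4, 5.5, 4.1,
    # grassland
    0.6, 3.0, 3.5, 0.0, 3.7,
    # water
    2.4, 1.0, 1.3, 1.9, 2.3, 1.2, 0.6,
    # built-up, unused
    1.0, 1.6)
  tab <- expand_composition()
  tab$region_id <- "national"
  tab <- tab[, c("region_id", "landuse", "item")]
  if (units == "Tg") {
    tab$Tg_per_yr <- tg
  } else {
    tab$kgN_per_yr <- tg * 1e9
    validate_flux_table(tab)
  }
  tab
}
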