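#' @keywords internal
"_PACKAGE"

#' Land-use classes of the nitrogen-input budget
#'
#' The six receiving land-use types tracked by the budget, with the integer
#' codes used in land-use rasters. Codes are stable across the package: ties
#' in class assignment resolve to the lowest code.
#'
#' @return Named integer vector (class name -> raster code).
#' @export
landuse_classes <- function() {
  c("cropland" = 1L, "forest" = 2L, "grassland" = 3L,
    "water" = 4L, "built-up" = 5L, "unused" = 6L)
}

#' Budget composition: which input items each land-use type receives
#'
#' Cropland receives seven items (fertilizer, deposition, irrigation, manure,
#' human excretion, cropland BNF, straw recycle); forest three; grassland
#' five; surface water seven (three runoff terms, three wastewater terms,
#' deposition); built-up and unused land receive deposition only.
#' Item names form a closed vocabulary; row order here is the report order.
#'
#' @return Named list: land-use class -> character vector of item names.
#' @export
budget_composition <- function() {
  list(
    "cropland"  = c("N fertilizer", "N deposition", "irrigation",
                    "livestock manure", "human excretion", "cropland BNF",
                    "straw recycle"),
    "forest"    = c("N fertilizer", "N deposition", "forest BNF"),
    "grassland" = c("N fertilizer", "grassland BNF", "N deposition",
                    "irrigation for artificial grassland", "livestock manure"),
    "water"     = c("cropland runoff", "livestock runoff", "forest runoff",
                    "human wastewater discharged", "industrial wastewater",
                    "WTP effluent", "N deposition"),
    "built-up"  = c("N deposition"),
    "unused"    = c("N deposition")
  )
}

#' Construct a single flux record
#'
#' One nitrogen flux: a source item delivered to a receiving land-use type,
#' in kg N/yr, attributed to an administrative region (or "national").
#'
#' @param landuse Receiving land-use class (one of [landuse_classes()] names).
#' @param item Flux item name from the closed budget vocabulary.
#' @param kgN_per_yr Magnitude in kg N per year, non-negative.
#' @param region_id Region identifier, default "national".
#' @return A one-row data.frame (a FluxTable of length one).
#' @export
flux_record <- function(landuse, item, kgN_per_yr, region_id = "national") {
  comp <- budget_composition()
  if (!landuse %in% names(comp))
    stop("unknown land-use class: '", landuse, "'", call. = FALSE)
  if (!item %in% comp[[landuse]])
    stop("item '", item, "' is not in the budget vocabulary for land use '",
         landuse, "'", call. = FALSE)
  if (!is.finite(kgN_per_yr) || kgN_per_yr < 0)
    stop("flux magnitude must be finite and >= 0, got ", kgN_per_yr,
         call. = FALSE)
  data.frame(region_id = as.character(region_id), landuse = landuse,
             item = item, kgN_per_yr = as.numeric(kgN_per_yr),
             stringsAsFactors = FALSE)
}

#' Bind and validate a flux table
#'
#' @param ... FluxTable data.frames (or a single list of them).
#' @return A validated flux table with unique (region_id, landuse, item) rows.
#' @export
flux_table <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !is.data.frame(parts[[1]]))
    parts <- parts[[1]]
  tab <- do.call(rbind, parts)
  rownames(tab) <- NULL
  validate_flux_table(tab)
  tab
}

#' Validate a flux table's structure and invariants
#'
#' Checks required columns, non-negative magnitudes, vocabulary membership,
#' and uniqueness of (region_id, landuse, item).
#'
#' @param tab A flux-table data.frame.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_flux_table <- function(tab) {
  need <- c("region_id", "landuse", "item", "kgN_per_yr")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("flux table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  comp <- budget_composition()
  bad_lu <- setdiff(unique(tab$landuse), names(comp))
  if (length(bad_lu))
    stop("unknown land-use class(es): ", paste(bad_lu, collapse = ", "),
         call. = FALSE)
  for (lu in unique(tab$landuse)) {
    bad <- setdiff(unique(tab$item[tab$landuse == lu]), comp[[lu]])
    if (length(bad))
      stop("item(s) outside the '", lu, "' vocabulary: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(tab$kgN_per_yr)) || any(tab$kgN_per_yr < 0))
    stop("flux magnitudes must be finite and >= 0", call. = FALSE)
  key <- paste(tab$region_id, tab$landuse, tab$item, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (region_id, landuse, item) rows in flux table",
         call. = FALSE)
  invisible(tab)
}

#' Read / write a flux table as CSV
#'
#' Columns: region_id, landuse, item, kgN_per_yr. Values are written with
#' full double precision (up to 17 significant digits) so a round trip is
#' exact for all practical purposes.
#'
#' @param tab Flux table.
#' @param path File path.
#' @return `read_flux_table` returns the validated table; `write_flux_table`
#'   returns `path` invisibly.
#' @export
write_flux_table <- function(tab, path) {
  validate_flux_table(tab)
  out <- tab
  out$kgN_per_yr <- sprintf("%.17g", out$kgN_per_yr)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_flux_table
#' @export
read_flux_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(region_id = "character"))
  tab$kgN_per_yr <- as.numeric(tab$kgN_per_yr)
  validate_flux_table(tab)
  tab
}

#' Sum regional records of a flux table into national records
#'
#' @param tab Flux table with regional rows.
#' @return Flux table with one "national" row per (landuse, item).
#' @export
nationalize <- function(tab) {
  reg <- tab[tab$region_id != "national", , drop = FALSE]
  if (!nrow(reg)) return(tab[tab$region_id == "national", , drop = FALSE])
  agg <- stats::aggregate(kgN_per_yr ~ landuse + item, data = reg, FUN = sum)
  agg$region_id <- "national"
  agg[, c("region_id", "landuse", "item", "kgN_per_yr")]
}

# Tg <-> kg conversions and the single report rounding rule (half-up, 1 dp)
#' Convert kg N/yr to Tg N/yr (1 Tg = 1e9 kg)
#' @param kg Numeric vector in kg.
#' @return Numeric vector in Tg.
#' @export
kg_to_tg <- function(kg) kg / 1e9

#' Round half-up to a fixed number of decimals
#'
#' Report tables print Tg values at one decimal with ties rounded away from
#' zero (so 0.05 -> 0.1), matching conventional budget-table formatting
#' rather than banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
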