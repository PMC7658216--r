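#' Livestock manure returned to a receiving land use
#'
#' Manure N input (kg/yr) from a region's herds: the sum over animal
#' categories of head count x excretion factor (kg N/head/yr) x return rate
#' (fraction of excreted N applied to the receiving land use). Cropland and
#' grassland carry separate return-rate vectors.
#'
#' @param region One-row AdminSet data.frame.
#' @param coeffs Coefficient library.
#' @param landuse Receiving land use, "cropland" (default) or "grassland".
#' @return A one-row flux table ("livestock manure").
#' @export
livestock_manure_flux <- function(region, coeffs, landuse = "cropland") {
  pop <- region_livestock(region)
  if (!landuse %in% names(coeffs$re_an))
    stop("no manure return-rate set for land use '", landuse, "'",
         call. = FALSE)
  re <- coeffs$re_an[[landuse]]
  gap <- setdiff(names(pop), intersect(names(coeffs$excre_an), names(re)))
  if (length(gap))
    stop("missing excretion/return coefficient for animal category: ",
         paste(gap, collapse = ", "), call. = FALSE)
  mag <- sum(pop * coeffs$excre_an[names(pop)] * re[names(pop)])
  # no application to a land use the region does not have
  areas <- region_landuse_areas(region)
  if (landuse %in% names(areas) && areas[[landuse]] == 0) mag <- 0
  flux_record(landuse, "livestock manure", mag, region$region_id)
}

#' Human excretion returned to cropland
#'
#' (urban population x urban return rate + rural population x rural return
#' rate) x per-person excretion factor.
#'
#' @inheritParams livestock_manure_flux
#' @return A one-row flux table ("human excretion", cropland).
#' @export
human_excretion_flux <- function(region, coeffs) {
  if (region$pop_urban < 0 || region$pop_rural < 0)
    stop("populations must be non-negative", call. = FALSE)
  mag <- (region$pop_urban * coeffs$re_ur +
            region$pop_rural * coeffs$re_ru) * coeffs$excre_hu
  areas <- region_landuse_areas(region)
  if ("cropland" %in% names(areas) && areas[["cropland"]] == 0) mag <- 0
  flux_record("cropland", "human excretion", mag, region$region_id)
}

#' Biological N fixation of a land-use class
#'
#' Cropland BNF is planting area x per-crop fixation rate summed over
#' crops; forest and grassland BNF are class area x a single class rate
#' (kg N/ha/yr).
#'
#' @inheritParams livestock_manure_flux
#' @param landuse "cropland", "forest" or "grassland".
#' @return A one-row flux table ("<class> BNF").
#' @export
bnf_flux <- function(region, coeffs, landuse) {
  if (landuse == "cropland") {
    area <- region_planting(region)
    nz <- names(area)[area > 0]
    gap <- setdiff(nz, names(coeffs$r_fix$crops))
    if (length(gap))
      stop("no fixation rate for crop(s): ", paste(gap, collapse = ", "),
           call. = FALSE)
    mag <- sum(area * coeffs$r_fix$crops[names(area)], na.rm = TRUE)
    item <- "cropland BNF"
  } else if (landuse %in% c("forest", "grassland")) {
    mag <- region_landuse_areas(region)[[landuse]] * coeffs$r_fix[[landuse]]
    item <- paste(landuse, "BNF")
  } else {
    stop("BNF is not defined for land use '", landuse, "'", call. = FALSE)
  }
  flux_record(landuse, item, mag, region$region_id)
}

#' Nationally uniform per-area fluxes
#'
#' Straw recycling and irrigation inputs use one national rate (kg N/ha/yr)
#' times the relevant land-use area of the region: cropland area for
#' "straw recycle" and "irrigation", grassland area for "irrigation for
#' artificial grassland".
#'
#' @inheritParams livestock_manure_flux
#' @param item One of the three uniform-rate items.
#' @return A one-row flux table.
#' @export
uniform_rate_flux <- function(region, coeffs, item) {
  target <- c("straw recycle" = "cropland", "irrigation" = "cropland",
              "irrigation for artificial grassland" = "grassland")
  if (!item %in% names(target))
    stop("'", item, "' is not a uniform-rate item", call. = FALSE)
  if (!item %in% names(coeffs$uniform_rates))
    stop("no uniform rate configured for item '", item, "'", call. = FALSE)
  lu <- target[[item]]
  mag <- coeffs$uniform_rates[[item]] * region_landuse_areas(region)[[lu]]
  flux_record(lu, item, mag, region$region_id)
}

#' Fertilizer input of a region to a land-use class
#'
#' County fertilizer consumption is activity data (kg N/yr) read off the
#' AdminSet, not derived from a rate.
#'
#' @inheritParams livestock_manure_flux
#' @param landuse "cropland", "forest" or "grassland".
#' @return A one-row flux table ("N fertilizer").
#' @export
fertilizer_flux <- function(region, landuse = "cropland") {
  col <- paste0("fertilizer_", gsub("-", "_", landuse))
  if (!col %in% names(region))
    stop("no fertilizer column for land use '", landuse, "'", call. = FALSE)
  flux_record(landuse, "N fertilizer", region[[col]], region$region_id)
}

regional_activity_fluxes <- function(region, coeffs) {
  flux_table(
    fertilizer_flux(region, "cropland"),
    uniform_rate_flux(region, coeffs, "irrigation"),
    livestock_manure_flux(region, coeffs, "cropland"),
    human_excretion_flux(region, coeffs),
    bnf_flux(region, coeffs, "cropland"),
    uniform_rate_flux(region, coeffs, "straw recycle"),
    fertilizer_flux(region, "forest"),
    bnf_flux(region, coeffs, "forest"),
    fertilizer_flux(region, "grassland"),
    bnf_flux(region, coeffs, "grassland"),
    uniform_rate_flux(region, coeffs, "irrigation for artificial grassland"),
    livestock_manure_flux(region, coeffs, "grassland")
  )
}

regional_wastewater_fluxes <- function(region, coeffs) {
  flux_table(
    flux_record("water", "human wastewater discharged",
                coeffs$wastewater_per_capita *
                  (region$pop_urban + region$pop_rural), region$region_id),
    flux_record("water", "industrial wastewater",
                coeffs$industrial_n_per_gdp * region$gdp, region$region_id),
    flux_record("water", "WTP effluent",
                coeffs$wtp_effluent_per_capita * region$pop_urban,
                region$region_id)
  )
}

sum_items <- function(tab, region_id, landuse, items) {
  sel <- tab$region_id == region_id & tab$landuse == landuse &
    tab$item %in% items
  sum(tab$kgN_per_yr[sel])
}

#' Assemble the full national (+ regional) N-input budget
#'
#' Computes every activity-derived flux for each county, attaches the
#' externally computed atmospheric-deposition records, derives the three
#' surface-water runoff items (runoff coefficient x N input of the source
#' subsystem) and the three wastewater items, and returns regional rows plus
#' national rows that are exact sums of the regional ones.
#'
#' Deposition enters as a flux table with one "N deposition" record per
#' land-use class; if it also carries regional rows (one per county per
#' class, e.g. zonal sums of the deposition maps), runoff is computed per
#' region and every item of the budget has regional rows. With
#' national-only deposition, deposition and runoff rows exist at national
#' level only.
#'
#' @param regions AdminSet (county rows are used).
#' @param coeffs Coefficient library.
#' @param deposition Flux table of "N deposition" records per class.
#' @return Flux table with the 24-row national composition plus regional rows.
#' @export
assemble_budget <- function(regions, coeffs, deposition) {
  validate_admin_set(regions)
  validate_flux_table(deposition)
  counties <- admin_counties(regions)
  if (!nrow(counties)) stop("AdminSet has no county rows", call. = FALSE)

  act <- lapply(seq_len(nrow(counties)), function(i)
    regional_activity_fluxes(counties[i, , drop = FALSE], coeffs))
  ww <- lapply(seq_len(nrow(counties)), function(i)
    regional_wastewater_fluxes(counties[i, , drop = FALSE], coeffs))
  reg <- flux_table(c(act, ww))

  dep_reg <- deposition[deposition$region_id != "national", , drop = FALSE]
  dep_nat <- deposition[deposition$region_id == "national", , drop = FALSE]
  comp <- budget_composition()
  if (!nrow(dep_nat)) dep_nat <- nationalize(dep_reg)
  gap <- setdiff(names(comp)[vapply(comp, function(x)
    "N deposition" %in% x, logical(1))], dep_nat$landuse)
  if (length(gap))
    stop("deposition table missing class(es): ",
         paste(gap, collapse = ", "), call. = FALSE)

  rc <- coeffs$runoff_coeffs
  runoff_rows <- function(tab, id) {
    crop_in <- sum_items(tab, id, "cropland", comp$cropland)
    manure <- sum_items(tab, id, "cropland", "livestock manure") +
      sum_items(tab, id, "grassland", "livestock manure")
    forest_in <- sum_items(tab, id, "forest", comp$forest)
    flux_table(
      flux_record("water", "cropland runoff", rc[["cropland"]] * crop_in, id),
      flux_record("water", "livestock runoff", rc[["livestock"]] * manure, id),
      flux_record("water", "forest runoff", rc[["forest"]] * forest_in, id)
    )
  }

  if (nrow(dep_reg)) {
    reg <- flux_table(reg, dep_reg)
    reg <- flux_table(reg, flux_table(lapply(unique(reg$region_id),
                                             function(id)
                                               runoff_rows(reg, id))))
    nat <- nationalize(reg)
  } else {
    nat <- nationalize(reg)
    nat <- flux_table(nat, dep_nat)
    nat <- flux_table(nat, runoff_rows(nat, "national"))
  }

  # order national rows in report order, regional rows after
  order_tab <- function(tab) {
    key <- expand_composition()
    idx <- match(paste(tab$landuse, tab$item, sep = "\r"),
                 paste(key$landuse, key$item, sep = "\r"))
    tab[order(idx), , drop = FALSE]
  }
  nat <- order_tab(nat)
  missing_rows <- setdiff(paste(expand_composition()$landuse,
                                expand_composition()$item, sep = " / "),
                          paste(nat$landuse, nat$item, sep = " / "))
  if (length(missing_rows))
    stop("assembled budget is missing: ",
         paste(missing_rows, collapse = "; "), call. = FALSE)
  out <- rbind(nat, order_tab(reg))
  rownames(out) <- NULL
  validate_flux_table(out)
  out
}

#' The 24 (land use, item) pairs of the budget in report order
#' @return Data.frame with columns landuse, item.
#' @export
expand_composition <- function() {
  comp <- budget_composition()
  do.call(rbind, lapply(names(comp), function(lu)
    data.frame(landuse = lu, item = comp[[lu]], stringsAsFactors = FALSE)))
}
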