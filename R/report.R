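#' Percentile screening of extreme records (QA/QC)
#'
#' Flags, per item group, records whose magnitude falls strictly outside
#' the [p_low, p_high] sample quantiles of that group (default p0.5 /
#' p99.5), emulating the exclusion of extreme values during data quality
#' control. Optionally excludes flagged records, with the remaining
#' records of each affected group rescaled so the group total is
#' preserved.
#'
#' @param tab Data.frame with at least the grouping and value columns.
#' @param value_col Numeric column screened (default "kgN_per_yr").
#' @param by Grouping column (default "item").
#' @param p_low,p_high Quantile bounds (defaults 0.005, 0.995).
#' @param exclude Drop flagged records from the screened table?
#' @param renormalize After exclusion, rescale each affected group to its
#'   pre-exclusion total?
#' @return List: `table` (input plus logical `qaqc_flag`), `report`
#'   (one row per flagged record), `screened` (table after optional
#'   exclusion/renormalization; equals the input when `exclude = FALSE`).
#' @export
qaqc_screen <- function(tab, value_col = "kgN_per_yr", by = "item",
                        p_low = 0.005, p_high = 0.995,
                        exclude = FALSE, renormalize = FALSE) {
  if (!value_col %in% names(tab) || !is.numeric(tab[[value_col]]))
    stop("value column '", value_col, "' missing or not numeric",
         call. = FALSE)
  flag <- logical(nrow(tab))
  groups <- if (by %in% names(tab)) tab[[by]] else rep("all", nrow(tab))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    x <- tab[[value_col]][idx]
    qs <- stats::quantile(x, c(p_low, p_high), names = FALSE, type = 7)
    flag[idx] <- x < qs[1] | x > qs[2]
    if (all(flag[idx]))
      stop("QA/QC would exclude every record of group '", g, "'",
           call. = FALSE)
  }
  out <- tab
  out$qaqc_flag <- flag
  report <- out[flag, , drop = FALSE]
  screened <- out
  if (exclude && any(flag)) {
    kept <- out[!flag, , drop = FALSE]
    if (renormalize) {
      gk <- if (by %in% names(kept)) kept[[by]] else rep("all", nrow(kept))
      for (g in unique(groups[flag])) {
        tot_before <- sum(tab[[value_col]][groups == g])
        sel <- gk == g
        tot_after <- sum(kept[[value_col]][sel])
        if (tot_after > 0)
          kept[[value_col]][sel] <- kept[[value_col]][sel] *
            (tot_before / tot_after)
      }
    }
    screened <- kept
  }
  list(table = out, report = report, screened = screened)
}

#' Format the national budget as a published-style summary
#'
#' Per-land-use item list in report order with magnitudes in Tg N/yr
#' (one decimal, half-up), per-land-use subtotals, grand total and each
#' land use's share of the grand total. Rounding is applied only at
#' presentation; subtotals and shares are computed on unrounded values.
#'
#' @param tab Flux table with national rows (regional rows are ignored).
#' @return List: `rows` (landuse, item, Tg), `subtotals` (landuse,
#'   Tg_subtotal, share_pct), `grand_total_Tg`, `grand_total_kg`,
#'   `text` (printable lines).
#' @export
budget_report <- function(tab) {
  if ("Tg_per_yr" %in% names(tab) && !"kgN_per_yr" %in% names(tab)) {
    tab$kgN_per_yr <- tab$Tg_per_yr * 1e9
  }
  validate_flux_table(tab)
  nat <- tab[tab$region_id == "national", , drop = FALSE]
  if (!nrow(nat)) stop("no national rows to report", call. = FALSE)
  key <- expand_composition()
  idx <- match(paste(nat$landuse, nat$item),
               paste(key$landuse, key$item))
  nat <- nat[order(idx), , drop = FALSE]

  rows <- data.frame(landuse = nat$landuse, item = nat$item,
                     Tg = round_half_up(kg_to_tg(nat$kgN_per_yr), 1),
                     stringsAsFactors = FALSE)
  sub_kg <- tapply(nat$kgN_per_yr, nat$landuse, sum)
  lus <- intersect(names(budget_composition()), names(sub_kg))
  grand_kg <- sum(nat$kgN_per_yr)
  subtotals <- data.frame(
    landuse = lus,
    Tg_subtotal = round_half_up(kg_to_tg(unname(sub_kg[lus])), 1),
    share_pct = round_half_up(100 * unname(sub_kg[lus]) / grand_kg, 1),
    stringsAsFactors = FALSE)

  text <- c("National reactive-nitrogen inputs by land-use type (Tg N/yr)",
            strrep("-", 60))
  for (lu in lus) {
    text <- c(text, toupper(lu))
    sel <- rows$landuse == lu
    text <- c(text, sprintf("  %-38s %6.1f", rows$item[sel], rows$Tg[sel]))
    text <- c(text, sprintf("  %-38s %6.1f  (%.1f%% of total)",
                            "subtotal",
                            subtotals$Tg_subtotal[subtotals$landuse == lu],
                            subtotals$share_pct[subtotals$landuse == lu]))
  }
  text <- c(text, strrep("-", 60),
            sprintf("  %-38s %6.1f", "GRAND TOTAL",
                    round_half_up(kg_to_tg(grand_kg), 1)))
  list(rows = rows, subtotals = subtotals,
       grand_total_Tg = round_half_up(kg_to_tg(grand_kg), 1),
       grand_total_kg = grand_kg, text = text)
}

#' Run the full pipeline on a synthetic (or equivalently structured) bundle
#'
#' Orchestrates budget assembly, column compositing, dasymetric
#' disaggregation, surface-water derivation, watershed aggregation and
#' reporting, with conservation audits at every allocation. Stages:
#'
#' 1. composite daily NO2/NH3 columns to monthly means, build the
#'    deposition index, allocate configured class totals (regional rows by
#'    county zonal sums);
#' 2. assemble the regional + national flux table;
#' 3. allocate each land item onto the grid by its proxy assignment
#'    (fertilizer/BNF/irrigation/straw uniformly over the class mask;
#'    manure by livestock density on the class mask; excretion by
#'    population on cropland);
#' 4. derive water-input maps (runoff = coefficient x source map,
#'    wastewater by socioeconomic proxies), book them into watersheds, and
#'    place the water land-use layer on water cells basin by basin;
#' 5. combine per-class and national maps and format the budget report.
#'
#' @param bundle A `synth_bundle` (or list with the same components).
#' @param out_dir Optional output directory; when given, tables, maps, a
#'   README manifest and a provenance file are written.
#' @return List: `budget` (flux table), `deposition` (module output),
#'   `item_maps` (nested list landuse -> item -> `grid_map`),
#'   `landuse_totals`, `national_total` (grid maps), `basin_table`,
#'   `report`, `audits` (conservation checks), `files` (when written).
#' @export
run_pipeline <- function(bundle, out_dir = NULL) {
  regions <- bundle$regions
  coeffs <- bundle$coefficients
  counties_r <- bundle$counties
  landuse_r <- bundle$landuse
  # fail fast: every proxy the stages below rely on must be present
  need_proxies <- c("population", "urban_population", "gdp", "livestock")
  miss <- setdiff(need_proxies, names(bundle$proxies))
  if (length(miss))
    stop("missing proxy grid(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  validate_admin_set(regions)
  validate_coefficients(coeffs)

  # --- deposition ------------------------------------------------------
  no2_m <- monthly_mean(bundle$columns$no2)
  nh3_m <- monthly_mean(bundle$columns$nh3)
  index <- deposition_index(no2_m, nh3_m,
                            coeffs$deposition_index_weights)
  dep <- deposition_by_landuse(index, landuse_r, coeffs$deposition_totals,
                               region_raster = counties_r,
                               regions = regions)

  # --- budget ----------------------------------------------------------
  budget <- assemble_budget(regions, coeffs, dep$table)
  nat <- budget[budget$region_id == "national", , drop = FALSE]

  # --- land disaggregation --------------------------------------------
  masks <- lapply(stats::setNames(nm = names(landuse_classes())),
                  function(cl) landuse_mask(landuse_r, cl))
  ones <- uniform_proxy(landuse_r)
  proxy_for <- function(item) {
    switch(item,
           "livestock manure" = bundle$proxies$livestock,
           "human excretion" = bundle$proxies$population,
           ones)
  }
  alloc_item <- function(lu, item) {
    if (item == "N deposition") return(dep$maps[[lu]])
    allocate_item(budget, lu, item, regions, counties_r,
                  proxy_for(item), masks[[lu]])
  }
  land_lus <- c("cropland", "forest", "grassland", "built-up", "unused")
  item_maps <- list()
  for (lu in land_lus)
    item_maps[[lu]] <- lapply(
      stats::setNames(nm = budget_composition()[[lu]]),
      function(item) alloc_item(lu, item))

  # --- surface water ---------------------------------------------------
  rc <- coeffs$runoff_coeffs
  crop_total_map <- combine_maps(item_maps$cropland)
  forest_total_map <- combine_maps(item_maps$forest)
  manure_map <- combine_maps(list(item_maps$cropland[["livestock manure"]],
                                  item_maps$grassland[["livestock manure"]]))
  ww <- wastewater_fluxes(regions, coeffs,
                          proxies = list(
                            population = bundle$proxies$population,
                            urban_population = bundle$proxies$urban_population,
                            gdp = bundle$proxies$gdp),
                          counties_r)
  water_src_maps <- list(
    "cropland runoff" = runoff_flux(crop_total_map, rc[["cropland"]],
                                    "cropland runoff")$map,
    "livestock runoff" = runoff_flux(manure_map, rc[["livestock"]],
                                     "livestock runoff")$map,
    "forest runoff" = runoff_flux(forest_total_map, rc[["forest"]],
                                  "forest runoff")$map,
    "human wastewater discharged" = ww[["human wastewater discharged"]]$map,
    "industrial wastewater" = ww[["industrial wastewater"]]$map,
    "WTP effluent" = ww[["WTP effluent"]]$map,
    "N deposition" = dep$maps$water)

  basin_table <- watershed_totals(water_src_maps, bundle$basins,
                                  bundle$basin_ids)

  # water land-use layer: each item's basin mass placed on the basin's
  # water cells (uniformly), falling back to all basin cells if none
  basin_code <- stats::setNames(names(bundle$basin_ids),
                                unname(bundle$basin_ids))
  item_maps$water <- lapply(stats::setNames(nm = names(water_src_maps)),
                            function(item) {
    bt <- basin_table[basin_table$item == item &
                        basin_table$basin_id != "unassigned", , drop = FALSE]
    fl <- stats::setNames(bt$kgN_per_yr, basin_code[bt$basin_id])
    suppressWarnings(allocate(fl, bundle$basins, ones, masks$water))
  })

  # --- combined maps and audits ---------------------------------------
  landuse_totals <- lapply(stats::setNames(nm = names(item_maps)),
                           function(lu) combine_maps(item_maps[[lu]]))
  national_total <- combine_maps(unname(landuse_totals))

  audits <- list()
  for (lu in names(item_maps)) for (item in names(item_maps[[lu]])) {
    expected <- sum(nat$kgN_per_yr[nat$landuse == lu & nat$item == item])
    got <- grid_total(item_maps[[lu]][[item]])
    audits[[length(audits) + 1L]] <- data.frame(
      landuse = lu, item = item, national_kg = expected, map_kg = got,
      rel_err = if (expected > 0) abs(got - expected) / expected else
        abs(got), stringsAsFactors = FALSE)
  }
  audits <- do.call(rbind, audits)

  report <- budget_report(budget)
  out <- list(budget = budget, deposition = dep, item_maps = item_maps,
              landuse_totals = landuse_totals,
              national_total = national_total,
              basin_table = basin_table, report = report, audits = audits)
  if (!is.null(out_dir))
    out$files <- write_pipeline_outputs(out, bundle, out_dir)
  out
}

# mirror of the published three-file structure: data dir + readme + sources
write_pipeline_outputs <- function(result, bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, paste0(...))
  files <- c()
  safe <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))
  write_flux_table(result$budget, p("flux_table.csv"))
  files["flux_table"] <- p("flux_table.csv")
  write_basin_table(result$basin_table, p("basin_table.csv"))
  files["basin_table"] <- p("basin_table.csv")
  writeLines(result$report$text, p("budget_report.txt"))
  files["report"] <- p("budget_report.txt")
  utils::write.csv(result$audits, p("conservation_audits.csv"),
                   row.names = FALSE)
  files["audits"] <- p("conservation_audits.csv")
  for (lu in names(result$item_maps))
    for (item in names(result$item_maps[[lu]])) {
      f <- p(safe(lu), "_", safe(item), ".asc")
      write_asc(result$item_maps[[lu]][[item]], f)
      files[paste0("map_", safe(lu), "_", safe(item))] <- f
    }
  for (lu in names(result$landuse_totals)) {
    f <- p(safe(lu), "_total.asc")
    write_asc(result$landuse_totals[[lu]], f)
    files[paste0("map_", safe(lu), "_total")] <- f
  }
  write_asc(result$national_total, p("national_total.asc"))
  files["map_national_total"] <- p("national_total.asc")
  write_coefficients(bundle$coefficients, p("coefficients_used.yaml"))
  files["coefficients"] <- p("coefficients_used.yaml")
  cfg_hash <- unname(tools::md5sum(p("coefficients_used.yaml")))

  readme <- c(
    "# Output manifest",
    "",
    "Data directory of the nitrogen-input budget run.",
    "",
    "## Files",
    "- flux_table.csv: all fluxes, columns region_id / landuse / item /",
    "  kgN_per_yr ('national' rows are exact sums of the regional rows).",
    "- basin_table.csv: surface-water inputs per watershed (basin_id,",
    "  item, kgN_per_yr; 'unassigned' collects cells outside all basins).",
    "- budget_report.txt: Tg N/yr summary by land use (1 Tg = 1e9 kg).",
    "- <landuse>_<item>.asc, <landuse>_total.asc, national_total.asc:",
    "  ESRI ASCII grids, kg N per 1 km cell (100 ha), row 1 = north.",
    "- conservation_audits.csv: per-flux map mass vs national magnitude.",
    "",
    "## Abbreviations and units",
    "- Nr: reactive nitrogen; BNF: biological N fixation;",
    "  WTP: wastewater treatment plant.",
    "- Magnitudes: kg N/yr internally, Tg N/yr in the report",
    "  (rounded half-up to 1 decimal).")
  writeLines(readme, p("README_outputs.md"))
  files["readme"] <- p("README_outputs.md")
  sources <- c(
    "# Provenance",
    sprintf("package: nbudget %s",
            as.character(utils::packageVersion("nbudget"))),
    sprintf("coefficient_config_md5: %s", cfg_hash),
    sprintf("synthetic_seed: %s", bundle$spec$seed),
    "inputs: synthetic country bundle (admin tables, land-use and proxy",
    "  rasters, daily trace-gas column stacks, watershed partition)",
    "coefficients: illustrative defaults shipped with the package;",
    "  deposition class totals as configured in coefficients_used.yaml")
  writeLines(sources, p("sources.txt"))
  files["sources"] <- p("sources.txt")
  invisible(files)
}
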