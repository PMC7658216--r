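#' Specification of a synthetic country
#'
#' Defines the study conditions of the synthetic test country: grid
#' geometry, administrative tiling, land-use class fractions, national
#' activity totals and the noise model of the daily trace-gas columns.
#' The same seed yields bit-identical outputs (R's default Mersenne-Twister
#' generator, seeded once at the start of generation).
#'
#' Defaults describe a 200 x 200 km country at 1 km resolution (one run in
#' seconds): 4 provinces of 25 counties each, a land-use mix dominated by
#' cropland and forest, 5 million inhabitants (40% urban), and column
#' fields observed on ~80% of days with 10% multiplicative noise.
#'
#' @param seed Integer RNG seed.
#' @param nrow,ncol Grid shape (cells); cellsize fixed at 1000 m
#'   (100 ha/cell).
#' @param prov_rc Provinces as a (rows, cols) tiling of the grid.
#' @param county_rc Counties as a (rows, cols) sub-tiling of each province.
#' @param landuse_fractions Named fractions over the six classes, summing
#'   to 1 (tolerance 1e-12).
#' @param pop_urban_total,pop_rural_total Persons.
#' @param gdp_total Currency units/yr.
#' @param livestock_totals Named head counts per animal category.
#' @param fertilizer_totals Named kg N/yr for cropland, forest, grassland.
#' @param crop_shares Named fractions of cropland area per crop, summing
#'   to 1.
#' @param deposition_totals Named kg N/yr per land-use class (the
#'   externally prescribed national deposition).
#' @param n_days Days in the synthetic month.
#' @param obs_prob Per-day, per-cell Bernoulli observation probability.
#' @param noise_sd Relative (multiplicative) noise s.d. of daily columns.
#' @param coarse_factor Fine cells per coarse column cell (per axis).
#' @param basin_rc Watershed partition as a (rows, cols) tiling.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(seed = 1L,
                       nrow = 200L, ncol = 200L,
                       prov_rc = c(2L, 2L), county_rc = c(5L, 5L),
                       landuse_fractions = c("cropland" = 0.30,
                                             "forest" = 0.25,
                                             "grassland" = 0.20,
                                             "water" = 0.05,
                                             "built-up" = 0.10,
                                             "unused" = 0.10),
                       pop_urban_total = 2e6, pop_rural_total = 3e6,
                       gdp_total = 8e10,
                       livestock_totals = c(pigs = 4e5, cattle = 1e5,
                                            sheep = 3e5, poultry = 5e6),
                       fertilizer_totals = c(cropland = 2.4e8,
                                             forest = 2.0e7,
                                             grassland = 5.0e6),
                       crop_shares = c(rice = 0.4, wheat = 0.3,
                                       maize = 0.2, soybean = 0.1),
                       deposition_totals = c("cropland" = 5.9e6,
                                             "forest" = 5.5e6,
                                             "grassland" = 3.5e6,
                                             "water" = 0.6e6,
                                             "built-up" = 1.0e6,
                                             "unused" = 1.6e6),
                       n_days = 30L, obs_prob = 0.8, noise_sd = 0.1,
                       coarse_factor = 8L, basin_rc = c(2L, 3L)) {
  if (abs(sum(landuse_fractions) - 1) > 1e-12)
    stop("landuse_fractions must sum to 1", call. = FALSE)
  if (!setequal(names(landuse_fractions), names(landuse_classes())))
    stop("landuse_fractions must cover the six classes", call. = FALSE)
  if (abs(sum(crop_shares) - 1) > 1e-12)
    stop("crop_shares must sum to 1", call. = FALSE)
  totals <- c(pop_urban_total, pop_rural_total, gdp_total,
              livestock_totals, fertilizer_totals, deposition_totals)
  if (any(!is.finite(totals)) || any(totals < 0))
    stop("all totals must be finite and >= 0", call. = FALSE)
  n_counties <- prod(prov_rc) * prod(county_rc)
  if (n_counties > nrow * ncol)
    stop("infeasible spec: more counties than grid cells", call. = FALSE)
  if (nrow %% (prov_rc[1] * county_rc[1]) != 0 ||
      ncol %% (prov_rc[2] * county_rc[2]) != 0)
    stop("county tiling must divide the grid evenly", call. = FALSE)
  structure(as.list(environment()), class = "synth_spec")
}

# smooth positive surface: low uniform floor + Gaussian bumps
bump_surface <- function(nr, nc, n_bumps, sigma_range, floor_level) {
  v <- matrix(floor_level, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_len(n_bumps)) {
    cr <- stats::runif(1, 1, nr); cc <- stats::runif(1, 1, nc)
    sg <- stats::runif(1, sigma_range[1], sigma_range[2])
    amp <- stats::runif(1, 0.5, 1.5)
    v <- v + amp * exp(-((rows - cr)^2 + (cols - cc)^2) / (2 * sg^2))
  }
  v
}

# block-average a fine matrix by an integer factor (truncates remainder)
block_mean <- function(m, f) {
  nr <- (nrow(m) %/% f) * f; nc <- (ncol(m) %/% f) * f
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  ri <- rep(seq_len(nr %/% f), each = f)
  ci <- rep(seq_len(nc %/% f), each = f)
  t(apply(rowsum(m, ri) / f, 1, function(r) rowsum(r, ci) / f))
}

rect_tiling <- function(nrow, ncol, tiles_rc, prefix, code_offset = 0L,
                        cellsize = 1000) {
  # cut points chosen so the tiles always cover the grid exactly, even
  # when the tile count does not divide the grid evenly
  rb <- floor(seq(0, nrow, length.out = tiles_rc[1] + 1))
  cb <- floor(seq(0, ncol, length.out = tiles_rc[2] + 1))
  codes <- matrix(NA_integer_, nrow, ncol)
  rects <- list()
  k <- 0L
  for (i in seq_len(tiles_rc[1])) for (j in seq_len(tiles_rc[2])) {
    k <- k + 1L
    rr <- (rb[i] + 1):rb[i + 1]
    cc <- (cb[j] + 1):cb[j + 1]
    codes[rr, cc] <- k + code_offset
    rects[[k]] <- data.frame(
      region_id = sprintf("%s%02d", prefix, k),
      raster_code = k + code_offset,
      xmin = (min(cc) - 1) * cellsize, xmax = max(cc) * cellsize,
      ymin = (nrow - max(rr)) * cellsize, ymax = (nrow - min(rr) + 1) *
        cellsize, stringsAsFactors = FALSE)
  }
  list(codes = codes, rects = do.call(rbind, rects))
}

#' Generate a synthetic country with machine-readable ground truth
#'
#' Builds the full input bundle every pipeline stage needs — administrative
#' hierarchy with activity data, land-use raster, proxy surfaces
#' (population, urban/rural population, GDP, livestock density), daily NO2
#' and NH3 column series around known monthly means, a watershed partition
#' — together with the coefficient library in force and the national
#' ground-truth flux table the budget must reproduce.
#'
#' Activity tables are derived from the rasters (zonal sums), so table and
#' raster are consistent by construction; ground-truth fluxes are computed
#' by direct arithmetic on the tables.
#'
#' @param spec A [synth_spec()].
#' @param out_dir Optional directory; when given, every bundle component is
#'   written there in its standard on-disk format (CSV, GeoJSON, ASCII
#'   grid, column-stack JSON+CSV, YAML) and a manifest is included.
#' @return A `synth_bundle` list: `regions`, `region_rects`, rasters
#'   (`landuse`, `counties`, `provinces`, `basins`), `proxies` (named list
#'   of grid maps), `columns` (list of two `column_series`),
#'   `column_truth` (list of the two noise-free monthly-mean grids),
#'   `basin_ids`, `coefficients`, `ground_truth`, `spec`, and `files`
#'   (named paths, when written).
#' @export
generate_synth_country <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  nr <- spec$nrow; nc <- spec$ncol
  cellsize <- 1000
  area_ha <- cellsize^2 / 1e4

  prov <- rect_tiling(nr, nc, spec$prov_rc, "P", cellsize = cellsize)
  n_prov <- prod(spec$prov_rc)
  cty <- rect_tiling(nr, nc, spec$prov_rc * spec$county_rc, "C",
                     cellsize = cellsize)
  county_codes <- cty$codes
  prov_of_county <- function(code) {
    # county tile index -> province tile containing it
    tr <- spec$prov_rc[1] * spec$county_rc[1]
    tc <- spec$prov_rc[2] * spec$county_rc[2]
    i <- (code - 1) %/% tc + 1; j <- (code - 1) %% tc + 1
    pi <- (i - 1) %/% spec$county_rc[1] + 1
    pj <- (j - 1) %/% spec$county_rc[2] + 1
    (pi - 1) * spec$prov_rc[2] + pj
  }

  classes <- landuse_classes()
  lu_codes <- matrix(sample(unname(classes), nr * nc, replace = TRUE,
                            prob = spec$landuse_fractions[names(classes)]),
                     nr, nc)

  urban <- bump_surface(nr, nc, 8, c(3, 8), 0.01)
  rural <- bump_surface(nr, nc, 15, c(10, 25), 0.5)
  gdp_s <- 0.7 * urban / max(urban) + 0.3 * bump_surface(nr, nc, 6,
                                                         c(5, 12), 0.05)
  lstk <- bump_surface(nr, nc, 12, c(8, 20), 0.2)
  scale_to <- function(m, total) if (sum(m) > 0) m * (total / sum(m)) else m
  urban <- scale_to(urban, spec$pop_urban_total)
  rural <- scale_to(rural, spec$pop_rural_total)
  gdp_s <- scale_to(gdp_s, spec$gdp_total)
  lstk <- scale_to(lstk, sum(spec$livestock_totals))

  gm <- function(v) grid_map(v, cellsize = cellsize)
  counties_r <- gm(county_codes)
  provinces_r <- gm(prov$codes)
  landuse_r <- gm(lu_codes)
  proxies <- list(population = gm(urban + rural),
                  urban_population = gm(urban),
                  rural_population = gm(rural),
                  gdp = gm(gdp_s),
                  livestock = gm(lstk))

  # county activity table from zonal sums (exact raster/table consistency)
  n_cty <- prod(spec$prov_rc * spec$county_rc)
  z <- function(m) {
    zs <- zonal_sum(gm(m), counties_r)
    out <- numeric(n_cty)
    out[as.integer(names(zs))] <- zs
    out
  }
  zu <- z(urban); zr <- z(rural); zg <- z(gdp_s); zl <- z(lstk)
  lu_cells <- sapply(names(classes), function(cl)
    z((lu_codes == classes[[cl]]) * 1))
  lu_area <- lu_cells * area_ha
  colnames(lu_area) <- lu_col(names(classes))

  lstk_total <- sum(spec$livestock_totals)
  lstk_share <- if (lstk_total > 0) zl / lstk_total else rep(0, n_cty)
  crop_area_nat <- sum(lu_area[, "lu_cropland"])
  area_share <- function(cl) {
    tot <- sum(lu_area[, lu_col(cl)])
    if (tot > 0) lu_area[, lu_col(cl)] / tot else rep(0, n_cty)
  }

  counties <- data.frame(
    region_id = cty$rects$region_id,
    parent_id = prov$rects$region_id[prov_of_county(seq_len(n_cty))],
    level = "county",
    raster_code = cty$rects$raster_code,
    pop_urban = zu, pop_rural = zr, gdp = zg,
    fertilizer_cropland = spec$fertilizer_totals[["cropland"]] *
      area_share("cropland"),
    fertilizer_forest = spec$fertilizer_totals[["forest"]] *
      area_share("forest"),
    fertilizer_grassland = spec$fertilizer_totals[["grassland"]] *
      area_share("grassland"),
    stringsAsFactors = FALSE)
  for (cat in names(spec$livestock_totals))
    counties[[paste0("livestock_", cat)]] <-
      spec$livestock_totals[[cat]] * lstk_share
  for (crop in names(spec$crop_shares))
    counties[[paste0("area_", crop)]] <-
      lu_area[, "lu_cropland"] * spec$crop_shares[[crop]]
  counties <- cbind(counties, as.data.frame(lu_area))

  num_cols <- names(counties)[vapply(counties, is.numeric, logical(1))]
  prov_rows <- do.call(rbind, lapply(seq_len(n_prov), function(p) {
    sub <- counties[prov_of_county(seq_len(n_cty)) == p, , drop = FALSE]
    row <- sub[1, , drop = FALSE]
    row$region_id <- prov$rects$region_id[p]
    row$parent_id <- NA_character_
    row$level <- "province"
    row$raster_code <- NA_integer_
    for (clm in setdiff(num_cols, "raster_code")) row[[clm]] <- sum(sub[[clm]])
    row
  }))
  regions <- rbind(prov_rows, counties)
  rownames(regions) <- NULL
  validate_admin_set(regions)

  # daily trace-gas columns: truth surfaces follow activity patterns
  f <- spec$coarse_factor
  no2_truth <- block_mean(gdp_s / max(gdp_s) + 0.05, f)
  nh3_truth <- block_mean(lstk / max(lstk) +
                            (lu_codes == classes[["cropland"]]) * 0.5 +
                            0.05, f)
  mk_series <- function(truth, species) {
    d <- spec$n_days
    fields <- array(NA_real_, c(d, nrow(truth), ncol(truth)))
    valid <- array(FALSE, dim(fields))
    for (day in seq_len(d)) {
      noise <- matrix(stats::rnorm(length(truth), 0, spec$noise_sd),
                      nrow(truth))
      fields[day, , ] <- pmax(truth * (1 + noise), 0)
      valid[day, , ] <- matrix(stats::runif(length(truth)) < spec$obs_prob,
                               nrow(truth))
    }
    column_series(species, fields, valid, cellsize = cellsize * f)
  }
  columns <- list(no2 = mk_series(no2_truth, "NO2"),
                  nh3 = mk_series(nh3_truth, "NH3"))
  column_truth <- list(
    no2 = grid_map(no2_truth, cellsize = cellsize * f),
    nh3 = grid_map(nh3_truth, cellsize = cellsize * f))

  basins <- rect_tiling(nr, nc, spec$basin_rc, "B", cellsize = cellsize)
  basin_ids <- stats::setNames(basins$rects$region_id,
                               as.character(basins$rects$raster_code))

  coeffs <- default_coefficients()
  coeffs$deposition_totals <- spec$deposition_totals
  coeffs <- validate_coefficients(coeffs)

  ground_truth <- synth_ground_truth(counties, coeffs)

  bundle <- list(regions = regions, region_rects = cty$rects,
                 province_rects = prov$rects,
                 landuse = landuse_r, counties = counties_r,
                 provinces = provinces_r,
                 basins = gm(basins$codes), basin_rects = basins$rects,
                 basin_ids = basin_ids,
                 proxies = proxies, columns = columns,
                 column_truth = column_truth,
                 coefficients = coeffs, ground_truth = ground_truth,
                 spec = spec)
  class(bundle) <- c("synth_bundle", "list")
  if (!is.null(out_dir)) bundle$files <- write_synth_bundle(bundle, out_dir)
  bundle
}

# national ground-truth flux table by direct arithmetic on the county table
synth_ground_truth <- function(counties, coeffs) {
  s <- function(col) sum(counties[[col]])
  crop_ha <- s("lu_cropland"); grass_ha <- s("lu_grassland")
  forest_ha <- s("lu_forest")
  # manure/excretion return is gated per county on presence of the
  # receiving land use (nothing can be applied to absent land)
  manure_to <- function(lu) {
    gate <- counties[[lu_col(lu)]] > 0
    re <- coeffs$re_an[[lu]]
    sum(vapply(names(coeffs$excre_an), function(cat)
      sum(counties[[paste0("livestock_", cat)]][gate]) *
        coeffs$excre_an[[cat]] * re[[cat]],
      numeric(1)))
  }
  gate_c <- counties$lu_cropland > 0
  excretion <- (sum(counties$pop_urban[gate_c]) * coeffs$re_ur +
                  sum(counties$pop_rural[gate_c]) * coeffs$re_ru) *
    coeffs$excre_hu
  cbnf <- sum(vapply(names(coeffs$r_fix$crops), function(cr) {
    col <- paste0("area_", cr)
    if (col %in% names(counties)) s(col) * coeffs$r_fix$crops[[cr]] else 0
  }, numeric(1)))
  u <- coeffs$uniform_rates
  dep <- coeffs$deposition_totals
  vals <- list(
    c("cropland", "N fertilizer", s("fertilizer_cropland")),
    c("cropland", "N deposition", dep[["cropland"]]),
    c("cropland", "irrigation", u[["irrigation"]] * crop_ha),
    c("cropland", "livestock manure", manure_to("cropland")),
    c("cropland", "human excretion", excretion),
    c("cropland", "cropland BNF", cbnf),
    c("cropland", "straw recycle", u[["straw recycle"]] * crop_ha),
    c("forest", "N fertilizer", s("fertilizer_forest")),
    c("forest", "N deposition", dep[["forest"]]),
    c("forest", "forest BNF", forest_ha * coeffs$r_fix$forest),
    c("grassland", "N fertilizer", s("fertilizer_grassland")),
    c("grassland", "grassland BNF", grass_ha * coeffs$r_fix$grassland),
    c("grassland", "N deposition", dep[["grassland"]]),
    c("grassland", "irrigation for artificial grassland",
      u[["irrigation for artificial grassland"]] * grass_ha),
    c("grassland", "livestock manure", manure_to("grassland")),
    c("water", "N deposition", dep[["water"]]),
    c("water", "human wastewater discharged",
      coeffs$wastewater_per_capita * (s("pop_urban") + s("pop_rural"))),
    c("water", "industrial wastewater",
      coeffs$industrial_n_per_gdp * s("gdp")),
    c("water", "WTP effluent",
      coeffs$wtp_effluent_per_capita * s("pop_urban")),
    c("built-up", "N deposition", dep[["built-up"]]),
    c("unused", "N deposition", dep[["unused"]])
  )
  tab <- flux_table(lapply(vals, function(v)
    flux_record(v[1], v[2], as.numeric(v[3]))))
  crop_in <- sum(tab$kgN_per_yr[tab$landuse == "cropland"])
  forest_in <- sum(tab$kgN_per_yr[tab$landuse == "forest"])
  manure <- manure_to("cropland") + manure_to("grassland")
  rc <- coeffs$runoff_coeffs
  tab <- flux_table(tab,
    flux_record("water", "cropland runoff", rc[["cropland"]] * crop_in),
    flux_record("water", "livestock runoff", rc[["livestock"]] * manure),
    flux_record("water", "forest runoff", rc[["forest"]] * forest_in))
  key <- expand_composition()
  idx <- match(paste(key$landuse, key$item), paste(tab$landuse, tab$item))
  out <- tab[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write every component of a synthetic bundle to a directory
#'
#' @param bundle A `synth_bundle`.
#' @param out_dir Directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_synth_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, paste0(...))
  files <- c(admin = p("admin.csv"), admin_geo = p("admin.geojson"),
             landuse = p("landuse.asc"), counties = p("counties.asc"),
             provinces = p("provinces.asc"), basins = p("basins.asc"),
             basins_geo = p("basins.geojson"),
             coefficients = p("coefficients.yaml"),
             ground_truth = p("ground_truth.csv"),
             spec = p("spec.json"))
  write_admin_set(bundle$regions, files[["admin"]])
  write_region_geojson(bundle$region_rects, files[["admin_geo"]])
  write_asc(bundle$landuse, files[["landuse"]])
  write_asc(bundle$counties, files[["counties"]])
  write_asc(bundle$provinces, files[["provinces"]])
  write_asc(bundle$basins, files[["basins"]])
  write_region_geojson(bundle$basin_rects, files[["basins_geo"]])
  write_coefficients(bundle$coefficients, files[["coefficients"]])
  write_flux_table(bundle$ground_truth, files[["ground_truth"]])
  sp <- bundle$spec
  jsonlite::write_json(unclass(sp)[!vapply(unclass(sp), is.function,
                                           logical(1))],
                       files[["spec"]], auto_unbox = TRUE, digits = NA)
  for (nm in names(bundle$proxies)) {
    f <- p("proxy_", nm, ".asc")
    write_asc(bundle$proxies[[nm]], f)
    files[paste0("proxy_", nm)] <- f
  }
  for (nm in names(bundle$columns)) {
    write_column_series(bundle$columns[[nm]], p("columns_", nm))
    files[paste0("columns_", nm, "_json")] <- p("columns_", nm, ".json")
    files[paste0("columns_", nm, "_csv")] <- p("columns_", nm, ".csv")
  }
  invisible(files)
}

#' Read a synthetic-country bundle back from a directory
#'
#' Reconstructs the in-memory bundle from the files written by
#' [write_synth_bundle()], so downstream stages can run from disk alone.
#'
#' @param dir Directory holding the bundle files.
#' @return A `synth_bundle` list (without the noise-free `column_truth`,
#'   which is not serialized).
#' @export
read_synth_bundle <- function(dir) {
  p <- function(...) file.path(dir, paste0(...))
  proxies <- list()
  for (f in list.files(dir, pattern = "^proxy_.*\\.asc$")) {
    nm <- sub("^proxy_", "", sub("\\.asc$", "", f))
    proxies[[nm]] <- read_asc(file.path(dir, f))
  }
  basin_rects <- read_region_geojson(p("basins.geojson"))
  spec <- jsonlite::read_json(p("spec.json"), simplifyVector = TRUE)
  bundle <- list(
    regions = read_admin_set(p("admin.csv")),
    region_rects = read_region_geojson(p("admin.geojson")),
    landuse = read_asc(p("landuse.asc")),
    counties = read_asc(p("counties.asc")),
    provinces = read_asc(p("provinces.asc")),
    basins = read_asc(p("basins.asc")),
    basin_rects = basin_rects,
    basin_ids = stats::setNames(basin_rects$region_id,
                                as.character(basin_rects$raster_code)),
    proxies = proxies,
    columns = list(no2 = read_column_series(p("columns_no2")),
                   nh3 = read_column_series(p("columns_nh3"))),
    coefficients = read_coefficients(p("coefficients.yaml")),
    ground_truth = read_flux_table(p("ground_truth.csv")),
    spec = spec)
  class(bundle) <- c("synth_bundle", "list")
  bundle
}
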