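test_that("the same seed yields bit-identical bundle files", {
  d1 <- file.path(tempdir(), "synth_a")
  d2 <- file.path(tempdir(), "synth_b")
  b1 <- generate_synth_country(small_spec(seed = 19), out_dir = d1)
  b2 <- generate_synth_country(small_spec(seed = 19), out_dir = d2)
  for (nm in names(b1$files)) {
    h1 <- unname(tools::md5sum(b1$files[[nm]]))
    h2 <- unname(tools::md5sum(b2$files[[nm]]))
    expect_identical(h1, h2)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("activity tables are exact zonal sums of the proxy rasters", {
  b <- generate_synth_country(small_spec())
  cty <- admin_counties(b$regions)
  zs_u <- zonal_sum(b$proxies$urban_population, b$counties)
  zs_g <- zonal_sum(b$proxies$gdp, b$counties)
  expect_identical(unname(zs_u[as.character(cty$raster_code)]),
                   cty$pop_urban)
  expect_identical(unname(zs_g[as.character(cty$raster_code)]), cty$gdp)
  # combined population raster closes against the table at 1e-12
  zs_p <- zonal_sum(b$proxies$population, b$counties)
  expect_equal(unname(zs_p[as.character(cty$raster_code)]),
               cty$pop_urban + cty$pop_rural, tolerance = 1e-12)
  # livestock density raster carries total head equivalents
  zs_l <- zonal_sum(b$proxies$livestock, b$counties)
  heads <- unname(rowSums(cty[, grep("^livestock_", names(cty))]))
  expect_equal(unname(zs_l[as.character(cty$raster_code)]), heads,
               tolerance = 1e-12)
  # land-use areas match raster cell counts
  crop_cells <- zonal_sum(landuse_mask(b$landuse, "cropland"), b$counties)
  expect_equal(unname(crop_cells[as.character(cty$raster_code)]) * 100,
               cty$lu_cropland)
})

test_that("province rows aggregate their counties and hierarchy closes", {
  b <- generate_synth_country(small_spec())
  expect_silent(validate_admin_set(b$regions))
  prov <- b$regions[b$regions$level == "province", ]
  cty <- admin_counties(b$regions)
  for (p in prov$region_id) {
    sub <- cty[cty$parent_id == p, ]
    expect_equal(prov$pop_urban[prov$region_id == p], sum(sub$pop_urban))
    expect_equal(prov$lu_forest[prov$region_id == p], sum(sub$lu_forest))
  }
})

test_that("ground truth closes across land uses and items", {
  b <- generate_synth_country(small_spec())
  gt <- b$ground_truth
  expect_equal(nrow(gt), 24)
  by_lu <- tapply(gt$kgN_per_yr, gt$landuse, sum)
  by_item <- tapply(gt$kgN_per_yr, gt$item, sum)
  expect_equal(sum(by_lu), sum(by_item))
  expect_true(all(gt$kgN_per_yr >= 0))
})

test_that("an all-cropland country has no other land inputs but deposition", {
  sp <- synth_spec(seed = 5, nrow = 40, ncol = 40, prov_rc = c(2, 1),
                   county_rc = c(2, 2), coarse_factor = 8, n_days = 5,
                   landuse_fractions = c("cropland" = 1, "forest" = 0,
                                         "grassland" = 0, "water" = 0,
                                         "built-up" = 0, "unused" = 0))
  b <- generate_synth_country(sp)
  gt <- b$ground_truth
  land <- gt[gt$landuse %in% c("forest", "grassland", "built-up",
                               "unused"), ]
  expect_true(all(land$kgN_per_yr[land$item != "N deposition"] == 0))
  expect_true(all(gt$kgN_per_yr[gt$landuse == "cropland" &
                                  gt$item == "N fertilizer"] > 0))
})

test_that("infeasible or inconsistent specs are rejected", {
  expect_error(synth_spec(nrow = 4, ncol = 4, prov_rc = c(2, 2),
                          county_rc = c(5, 5)), "infeasible")
  expect_error(synth_spec(landuse_fractions = c(
    "cropland" = 0.9, "forest" = 0.2, "grassland" = 0, "water" = 0,
    "built-up" = 0, "unused" = 0)), "sum to 1")
})

test_that("admin, coefficient and geojson serializations round-trip", {
  b <- generate_synth_country(small_spec())
  d <- file.path(tempdir(), "rt")
  dir.create(d, showWarnings = FALSE)
  f1 <- file.path(d, "admin.csv")
  write_admin_set(b$regions, f1)
  r2 <- read_admin_set(f1)
  expect_identical(r2$pop_urban, b$regions$pop_urban)
  expect_identical(r2$lu_cropland, b$regions$lu_cropland)
  f2 <- file.path(d, "co.yaml")
  write_coefficients(b$coefficients, f2)
  co2 <- read_coefficients(f2)
  expect_equal(co2$excre_an, b$coefficients$excre_an)
  expect_equal(co2$deposition_totals, b$coefficients$deposition_totals)
  f3 <- file.path(d, "regions.geojson")
  write_region_geojson(b$region_rects, f3)
  rr <- read_region_geojson(f3)
  expect_identical(rr$region_id, b$region_rects$region_id)
  expect_identical(rr$xmin, b$region_rects$xmin)
  unlink(d, recursive = TRUE)
})

test_that("a written bundle reloads into an equivalent working bundle", {
  d <- file.path(tempdir(), "bundle_rt")
  b <- generate_synth_country(small_spec(seed = 3), out_dir = d)
  b2 <- read_synth_bundle(d)
  expect_identical(b2$landuse$values, b$landuse$values)
  expect_identical(b2$proxies$gdp$values, b$proxies$gdp$values)
  expect_identical(b2$columns$no2$fields, b$columns$no2$fields)
  expect_equal(b2$ground_truth$kgN_per_yr, b$ground_truth$kgN_per_yr)
  expect_equal(b2$coefficients$runoff_coeffs, b$coefficients$runoff_coeffs)
  # the reloaded bundle drives the pipeline to the same national budget
  n1 <- nationalize(run_pipeline(b)$budget)
  n2 <- nationalize(run_pipeline(b2)$budget)
  m <- merge(n1, n2, by = c("landuse", "item"))
  expect_equal(m$kgN_per_yr.x, m$kgN_per_yr.y, tolerance = 1e-12)
  unlink(d, recursive = TRUE)
})
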