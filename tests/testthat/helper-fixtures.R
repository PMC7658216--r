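# in-code fixtures shared by the suite

# one-county AdminSet row with every activity column the budget needs
make_county <- function(region_id = "C01",
                        pop_urban = 10000, pop_rural = 5000, gdp = 1e8,
                        fertilizer_cropland = 50000,
                        fertilizer_forest = 2000,
                        fertilizer_grassland = 500,
                        livestock = c(pigs = 200, cattle = 50),
                        planting = c(soybean = 40, rice = 60),
                        lu = c(cropland = 100, forest = 80, grassland = 60,
                               water = 10, "built-up" = 20, unused = 30),
                        raster_code = 1L) {
  row <- data.frame(region_id = region_id, parent_id = "P01",
                    level = "county", raster_code = raster_code,
                    pop_urban = pop_urban, pop_rural = pop_rural,
                    gdp = gdp,
                    fertilizer_cropland = fertilizer_cropland,
                    fertilizer_forest = fertilizer_forest,
                    fertilizer_grassland = fertilizer_grassland,
                    stringsAsFactors = FALSE)
  for (cat in names(livestock)) row[[paste0("livestock_", cat)]] <-
    unname(livestock[cat])
  for (cr in names(planting)) row[[paste0("area_", cr)]] <-
    unname(planting[cr])
  for (cl in names(lu)) row[[paste0("lu_", gsub("-", "_", cl))]] <-
    unname(lu[cl])
  row
}

# coefficient library with transparent hand-checkable values
make_coeffs <- function() {
  co <- default_coefficients()
  co$excre_an <- c(pigs = 8, cattle = 40)
  co$re_an <- list(cropland = c(pigs = 0.25, cattle = 0.1),
                   grassland = c(pigs = 0.0, cattle = 0.2))
  co$excre_hu <- 4; co$re_ur <- 0.1; co$re_ru <- 0.4
  co$r_fix$crops <- c(soybean = 80, rice = 20)
  validate_coefficients(co)
}

# small synthetic country used by most spatial tests (seconds to build)
small_spec <- function(seed = 11) {
  synth_spec(seed = seed, nrow = 40, ncol = 40, prov_rc = c(2, 1),
             county_rc = c(2, 2), coarse_factor = 8, n_days = 10,
             basin_rc = c(2, 2))
}
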