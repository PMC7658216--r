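test_that("runoff is coefficient x source, in map and record", {
  src <- grid_map(matrix(c(100, 300, 0, 600), 2, 2))
  z <- runoff_flux(src, 0, "cropland runoff")
  expect_true(all(z$map$values == 0))
  expect_equal(z$record$kgN_per_yr, 0)
  r <- runoff_flux(src, 0.1, "cropland runoff")
  expect_equal(grid_total(r$map), 100)
  expect_equal(r$record$kgN_per_yr, 100)
  # spatial pattern inherited: argmax of runoff = argmax of source
  expect_equal(which.max(r$map$values), which.max(src$values))
  # linearity in coefficient and in source mass
  r2 <- runoff_flux(src, 0.2, "cropland runoff")
  expect_equal(r2$map$values, 2 * r$map$values)
  src2 <- src; src2$values <- src$values * 3
  expect_equal(runoff_flux(src2, 0.1, "cropland runoff")$record$kgN_per_yr,
               300)
  expect_error(runoff_flux(src, 1.2, "cropland runoff"), "fraction")
})

test_that("wastewater magnitudes follow population and GDP", {
  co <- make_coeffs()
  regions <- rbind(make_county("C01", pop_urban = 30000, pop_rural = 10000,
                               gdp = 2e8, raster_code = 1L),
                   make_county("C02", pop_urban = 10000, pop_rural = 10000,
                               gdp = 1e8, raster_code = 2L))
  rr <- grid_map(matrix(c(1, 1, 2, 2), 2, 2))
  set.seed(8)
  proxies <- list(population = grid_map(matrix(runif(4), 2, 2)),
                  urban_population = grid_map(matrix(runif(4), 2, 2)),
                  gdp = grid_map(matrix(runif(4), 2, 2)))
  ww <- wastewater_fluxes(regions, co, proxies, rr)
  expect_equal(ww[["human wastewater discharged"]]$record$kgN_per_yr,
               co$wastewater_per_capita * 60000)
  expect_equal(ww[["industrial wastewater"]]$record$kgN_per_yr,
               co$industrial_n_per_gdp * 3e8)
  expect_equal(ww[["WTP effluent"]]$record$kgN_per_yr,
               co$wtp_effluent_per_capita * 40000)
  # two-city proportionality: each region's map mass tracks its share
  zs <- zonal_sum(ww[["human wastewater discharged"]]$map, rr)
  expect_equal(zs[["1"]] / zs[["2"]], 40000 / 20000)
  # doubling population doubles the national magnitude
  regions2 <- regions
  regions2$pop_urban <- regions$pop_urban * 2
  regions2$pop_rural <- regions$pop_rural * 2
  ww2 <- wastewater_fluxes(regions2, co, proxies, rr)
  expect_equal(ww2[["human wastewater discharged"]]$record$kgN_per_yr,
               2 * ww[["human wastewater discharged"]]$record$kgN_per_yr)
  # zero GDP everywhere -> zero industrial map
  regions0 <- regions; regions0$gdp <- 0
  ww0 <- wastewater_fluxes(regions0, co, proxies, rr)
  expect_true(all(ww0[["industrial wastewater"]]$map$values == 0))
  expect_error(wastewater_fluxes(regions, co, proxies["gdp"], rr),
               "missing proxy")
})

test_that("watershed totals partition national totals exactly", {
  set.seed(21)
  m1 <- grid_map(matrix(rexp(64), 8, 8))
  m2 <- grid_map(matrix(runif(64), 8, 8))
  maps <- list("cropland runoff" = m1, "WTP effluent" = m2)
  # one basin covering everything: basin total = national total
  one <- grid_map(matrix(1L, 8, 8))
  bt <- watershed_totals(maps, one)
  expect_equal(bt$kgN_per_yr[bt$basin_id == "1" &
                               bt$item == "cropland runoff"],
               grid_total(m1))
  # two equal-mass half-domains split 50/50
  half <- grid_map(matrix(rep(c(1L, 2L), each = 32), 8, 8))
  sym <- grid_map(matrix(1, 8, 8))
  bts <- watershed_totals(list("WTP effluent" = sym), half)
  expect_equal(bts$kgN_per_yr[bts$basin_id == "1" ],
               bts$kgN_per_yr[bts$basin_id == "2"])
  # random partition: basin sums + unassigned = national, to 1e-9
  part <- grid_map(matrix(sample(c(1:4, NA), 64, TRUE), 8, 8))
  btr <- watershed_totals(maps, part)
  for (item in names(maps)) {
    tot <- sum(btr$kgN_per_yr[btr$item == item])
    expect_lt(abs(tot - grid_total(maps[[item]])) /
                grid_total(maps[[item]]), 1e-9)
  }
  expect_error(watershed_totals(list(), one), "no water-input maps")
  expect_error(watershed_totals(maps, grid_map(matrix(NA_real_, 8, 8))),
               "no basins")
})
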