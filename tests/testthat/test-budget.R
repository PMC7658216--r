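test_that("livestock manure flux is the sum of head x excretion x return", {
  co <- make_coeffs()
  # single category: 1000 head x 10 kg/head x 0.5 return
  co1 <- co
  co1$excre_an <- c(pigs = 10)
  co1$re_an <- list(cropland = c(pigs = 0.5), grassland = c(pigs = 0))
  r1 <- make_county(livestock = c(pigs = 1000))
  expect_equal(livestock_manure_flux(r1, co1)$kgN_per_yr, 5000)

  # zero return rate gives zero flux
  co0 <- co1
  co0$re_an$cropland <- c(pigs = 0)
  expect_equal(livestock_manure_flux(r1, co0)$kgN_per_yr, 0)

  # two categories, hand-summed: 200*8*0.25 + 50*40*0.1 = 400 + 200
  r2 <- make_county(livestock = c(pigs = 200, cattle = 50))
  rec <- livestock_manure_flux(r2, co)
  expect_equal(rec$kgN_per_yr, 600)
  expect_equal(rec$landuse, "cropland")
  expect_equal(rec$item, "livestock manure")
})

test_that("a present animal category without coefficients is an error", {
  co <- make_coeffs()
  r <- make_county(livestock = c(pigs = 10, camels = 5))
  expect_error(livestock_manure_flux(r, co), "camels")
})

test_that("human excretion follows (urb x RE_ur + rur x RE_ru) x EXCRE", {
  co <- make_coeffs()
  r <- make_county(pop_urban = 10000, pop_rural = 5000)
  # (10000*0.1 + 5000*0.4) * 4 = 12000
  expect_equal(human_excretion_flux(r, co)$kgN_per_yr, 12000)

  co0 <- co; co0$re_ur <- 0; co0$re_ru <- 0
  expect_equal(human_excretion_flux(r, co0)$kgN_per_yr, 0)

  # degenerate all-urban, full return: POP_ur x EXCRE exactly
  co1 <- co; co1$re_ur <- 1
  r1 <- make_county(pop_urban = 7777, pop_rural = 0)
  expect_equal(human_excretion_flux(r1, co1)$kgN_per_yr, 7777 * 4)

  r_bad <- make_county(); r_bad$pop_rural <- -1
  expect_error(human_excretion_flux(r_bad, co), "non-negative")
})

test_that("BNF is planting area x fixation rate per class", {
  co <- make_coeffs()
  # single crop 100 ha x 15 kg/ha
  co1 <- co; co1$r_fix$crops <- c(rice = 15)
  r1 <- make_county(planting = c(rice = 100))
  expect_equal(bnf_flux(r1, co1, "cropland")$kgN_per_yr, 1500)
  r0 <- make_county(planting = c(rice = 0))
  expect_equal(bnf_flux(r0, co1, "cropland")$kgN_per_yr, 0)

  # two crops hand-summed: 40*80 + 60*20 = 3200 + 1200
  r2 <- make_county(planting = c(soybean = 40, rice = 60))
  expect_equal(bnf_flux(r2, co, "cropland")$kgN_per_yr, 4400)

  # class-rate BNF for forest and grassland
  expect_equal(bnf_flux(r2, co, "forest")$kgN_per_yr, 80 * co$r_fix$forest)
  expect_equal(bnf_flux(r2, co, "grassland")$kgN_per_yr,
               60 * co$r_fix$grassland)
  expect_error(bnf_flux(r2, co, "water"), "not defined")
})

test_that("uniform-rate items scale with the relevant land-use area", {
  co <- make_coeffs()
  co$uniform_rates[["irrigation"]] <- 10
  r <- make_county(lu = c(cropland = 50, forest = 0, grassland = 30,
                          water = 0, "built-up" = 0, unused = 0))
  expect_equal(uniform_rate_flux(r, co, "irrigation")$kgN_per_yr, 500)
  co0 <- co; co0$uniform_rates[["irrigation"]] <- 0
  expect_equal(uniform_rate_flux(r0 <- r, co0, "irrigation")$kgN_per_yr, 0)

  # two regions sharing a national rate: flux ratio equals area ratio
  r30 <- make_county(region_id = "A", lu = c(cropland = 30, forest = 0,
                                             grassland = 0, water = 0,
                                             "built-up" = 0, unused = 0))
  r70 <- make_county(region_id = "B", lu = c(cropland = 70, forest = 0,
                                             grassland = 0, water = 0,
                                             "built-up" = 0, unused = 0))
  f30 <- uniform_rate_flux(r30, co, "irrigation")$kgN_per_yr
  f70 <- uniform_rate_flux(r70, co, "irrigation")$kgN_per_yr
  expect_equal(f30 / f70, 30 / 70)
  expect_error(uniform_rate_flux(r, co, "N fertilizer"),
               "not a uniform-rate item")
})

test_that("equations match an independent hand oracle on random draws", {
  set.seed(4021)
  for (i in 1:120) {
    cats <- paste0("a", 1:sample(1:5, 1))
    pop <- stats::setNames(runif(length(cats), 0, 1e5), cats)
    ex <- stats::setNames(runif(length(cats), 0, 50), cats)
    re <- stats::setNames(runif(length(cats)), cats)
    co <- default_coefficients()
    co$excre_an <- ex
    co$re_an <- list(cropland = re, grassland = re * 0)
    co$excre_hu <- runif(1, 0, 10)
    co$re_ur <- runif(1); co$re_ru <- runif(1)
    crops <- paste0("c", 1:sample(1:4, 1))
    co$r_fix$crops <- stats::setNames(runif(length(crops), 0, 100), crops)
    co <- validate_coefficients(co)
    pu <- runif(1, 0, 1e6); pr <- runif(1, 0, 1e6)
    ar <- stats::setNames(runif(length(crops), 0, 1e4), crops)
    r <- make_county(pop_urban = pu, pop_rural = pr, livestock = pop,
                     planting = ar)
    # oracle: explicit per-category loop
    m <- 0; for (ct in cats) m <- m + pop[[ct]] * ex[[ct]] * re[[ct]]
    b <- 0; for (cr in crops) b <- b + ar[[cr]] * co$r_fix$crops[[cr]]
    h <- (pu * co$re_ur + pr * co$re_ru) * co$excre_hu
    expect_equal(livestock_manure_flux(r, co)$kgN_per_yr, m,
                 tolerance = 1e-12)
    expect_equal(human_excretion_flux(r, co)$kgN_per_yr, h,
                 tolerance = 1e-12)
    expect_equal(bnf_flux(r, co, "cropland")$kgN_per_yr, b,
                 tolerance = 1e-12)
  }
})

test_that("fluxes are homogeneous of degree one in activity data", {
  co <- make_coeffs()
  r <- make_county()
  k <- 3.7
  rk <- r
  for (cl in c("pop_urban", "pop_rural", "gdp", "fertilizer_cropland",
               grep("^(livestock_|area_|lu_)", names(r), value = TRUE)))
    rk[[cl]] <- r[[cl]] * k
  for (f in list(function(x) livestock_manure_flux(x, co)$kgN_per_yr,
                 function(x) human_excretion_flux(x, co)$kgN_per_yr,
                 function(x) bnf_flux(x, co, "cropland")$kgN_per_yr,
                 function(x) uniform_rate_flux(x, co,
                                               "straw recycle")$kgN_per_yr))
    expect_equal(f(rk), k * f(r))
})

test_that("manure and excretion are not applied to absent land uses", {
  co <- make_coeffs()
  r <- make_county(lu = c(cropland = 0, forest = 0, grassland = 0,
                          water = 10, "built-up" = 5, unused = 5))
  expect_equal(livestock_manure_flux(r, co, "cropland")$kgN_per_yr, 0)
  expect_equal(livestock_manure_flux(r, co, "grassland")$kgN_per_yr, 0)
  expect_equal(human_excretion_flux(r, co)$kgN_per_yr, 0)
})

national_dep <- function(co) {
  flux_table(lapply(names(co$deposition_totals), function(cl)
    flux_record(cl, "N deposition", co$deposition_totals[[cl]])))
}

test_that("assembled budget has exactly the published composition", {
  co <- make_coeffs()
  regions <- rbind(make_county("C01", raster_code = 1L),
                   make_county("C02", raster_code = 2L, pop_urban = 3000))
  tab <- assemble_budget(regions, co, national_dep(co))
  nat <- tab[tab$region_id == "national", ]
  key <- expand_composition()
  expect_equal(nrow(nat), 24)
  expect_setequal(paste(nat$landuse, nat$item),
                  paste(key$landuse, key$item))
  # additivity: national = sum of regional rows for every regional item
  reg <- tab[tab$region_id != "national", ]
  for (i in seq_len(nrow(nat))) {
    sel <- reg$landuse == nat$landuse[i] & reg$item == nat$item[i]
    if (any(sel))
      expect_equal(nat$kgN_per_yr[i], sum(reg$kgN_per_yr[sel]))
  }
})

test_that("with all coefficients zero only fertilizer rows are nonzero", {
  co <- make_coeffs()
  co$excre_an[] <- 0; co$excre_hu <- 0
  co$r_fix$crops[] <- 0; co$r_fix$forest <- 0; co$r_fix$grassland <- 0
  co$uniform_rates[] <- 0
  co$runoff_coeffs[] <- 0
  co$wastewater_per_capita <- 0; co$wtp_effluent_per_capita <- 0
  co$industrial_n_per_gdp <- 0
  co$deposition_totals[] <- 0
  co <- validate_coefficients(co)
  tab <- assemble_budget(make_county(), co, national_dep(co))
  nz <- tab[tab$kgN_per_yr > 0, ]
  expect_true(all(nz$item == "N fertilizer"))
  expect_true(any(nz$kgN_per_yr > 0))
})

test_that("flux tables validate their vocabulary and round-trip CSV", {
  expect_error(flux_record("cropland", "cropland runoff", 1), "vocabulary")
  expect_error(flux_record("ocean", "N deposition", 1), "unknown land-use")
  expect_error(flux_record("cropland", "N fertilizer", -5), ">= 0")
  tab <- flux_table(flux_record("cropland", "N fertilizer", 1 / 3, "A"),
                    flux_record("water", "WTP effluent", 2.5e9, "A"))
  expect_error(flux_table(tab, tab), "duplicate")
  f <- tempfile(fileext = ".csv")
  write_flux_table(tab, f)
  expect_identical(read_flux_table(f)$kgN_per_yr, tab$kgN_per_yr)
})
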