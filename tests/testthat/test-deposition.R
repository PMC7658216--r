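mk_series <- function(vals, valid = NULL) {
  # vals: list of daily matrices
  d <- length(vals)
  nr <- nrow(vals[[1]]); nc <- ncol(vals[[1]])
  fields <- array(NA_real_, c(d, nr, nc))
  for (i in seq_len(d)) fields[i, , ] <- vals[[i]]
  v <- if (is.null(valid)) NULL else {
    a <- array(TRUE, c(d, nr, nc))
    for (i in seq_len(d)) a[i, , ] <- valid[[i]]
    a
  }
  column_series("NO2", fields, v)
}

test_that("monthly mean is the arithmetic mean over valid days", {
  s <- mk_series(list(matrix(2, 1, 1), matrix(4, 1, 1), matrix(6, 1, 1)))
  expect_equal(monthly_mean(s)$values[1, 1], 4)
  # masked middle day excluded: mean(2, 6) = 4
  s2 <- mk_series(list(matrix(2, 1, 1), matrix(99, 1, 1), matrix(6, 1, 1)),
                  valid = list(matrix(TRUE, 1, 1), matrix(FALSE, 1, 1),
                               matrix(TRUE, 1, 1)))
  expect_equal(monthly_mean(s2)$values[1, 1], 4)
  # all days masked -> nodata
  s3 <- mk_series(list(matrix(1, 1, 1)), valid = list(matrix(FALSE, 1, 1)))
  expect_true(is.na(monthly_mean(s3)$values[1, 1]))
  expect_error(monthly_mean(list()), "empty")
})

test_that("monthly mean equals a brute-force per-cell loop", {
  set.seed(77)
  d <- 12; nr <- 6; nc <- 5
  fields <- array(runif(d * nr * nc), c(d, nr, nc))
  valid <- array(runif(d * nr * nc) < 0.7, c(d, nr, nc))
  s <- column_series("NH3", fields, valid)
  got <- monthly_mean(s)$values
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    xs <- c(); n <- 0
    for (day in seq_len(d)) if (valid[day, i, j]) {
      xs <- c(xs, fields[day, i, j]); n <- n + 1
    }
    if (n == 0) expect_true(is.na(got[i, j])) else
      expect_identical(got[i, j], sum(xs) / n)
  }
})

test_that("deposition index weights and normalizes the two columns", {
  no2 <- grid_map(matrix(c(1, 2, 3, 4), 2, 2))
  nh3 <- grid_map(matrix(c(4, 3, 2, 1), 2, 2))
  # weight (1, 0): index proportional to NO2 alone
  ix <- deposition_index(no2, nh3, c(1, 0))
  expect_equal(ix$values, no2$values / 4)
  # uniform columns give a uniform index
  u <- grid_map(matrix(5, 2, 2))
  expect_true(all(deposition_index(u, u)$values == 1))
  # invariance under common rescaling of both inputs
  s1 <- deposition_index(no2, nh3)
  no2b <- no2; no2b$values <- no2$values * 1e5
  nh3b <- nh3; nh3b$values <- nh3$values * 1e5
  expect_equal(deposition_index(no2b, nh3b)$values, s1$values)
  # bimodal columns: index maximum co-located with column maximum
  set.seed(3)
  m1 <- matrix(runif(100, 0, 0.1), 10, 10); m1[2, 2] <- 5
  m2 <- matrix(runif(100, 0, 0.1), 10, 10); m2[2, 2] <- 7
  ixb <- deposition_index(grid_map(m1), grid_map(m2))
  expect_equal(which.max(ixb$values), which.max(m1))
  expect_error(deposition_index(no2, grid_map(matrix(1, 3, 3))),
               "mismatch")
  expect_error(deposition_index(no2, nh3, c(0, 0)), "not both zero")
})

test_that("nearest-cell resampling is block-constant", {
  coarse <- grid_map(matrix(1:4, 2, 2), cellsize = 2000)
  fine <- grid_map(matrix(0, 4, 4), cellsize = 1000)
  r <- resample_nearest(coarse, fine)
  expect_equal(r$values[1:2, 1:2], matrix(coarse$values[1, 1], 2, 2))
  expect_equal(r$values[3:4, 3:4], matrix(coarse$values[2, 2], 2, 2))
})

test_that("deposition allocation reproduces configured class totals", {
  # uniform index over a single class of n cells: total / n per cell
  lu <- grid_map(matrix(1, 4, 4))
  ix <- grid_map(matrix(2, 4, 4))
  totals <- c("cropland" = 32, "forest" = 0, "grassland" = 0,
              "water" = 0, "built-up" = 0, "unused" = 0)
  out <- deposition_by_landuse(ix, lu, totals)
  expect_true(all(out$maps$cropland$values == 2))
  # published per-class totals are conserved through a mixed landscape
  b <- generate_synth_country(small_spec())
  tg <- c("cropland" = 5.9, "forest" = 5.5, "grassland" = 3.5,
          "water" = 0.6, "built-up" = 1.0, "unused" = 1.6) * 1e9
  ix2 <- deposition_index(monthly_mean(b$columns$no2),
                          monthly_mean(b$columns$nh3))
  out2 <- deposition_by_landuse(ix2, b$landuse, tg)
  tab <- out2$table
  for (cl in names(tg))
    expect_equal(tab$kgN_per_yr[tab$landuse == cl], unname(tg[cl]))
  # zonal re-aggregation of the fine maps by class matches exactly
  for (cl in names(tg)) {
    mass <- grid_total(out2$maps[[cl]])
    expect_lt(abs(mass - tg[[cl]]) / tg[[cl]], 1e-9)
    onclass <- out2$maps[[cl]]$values[b$landuse$values !=
                                        landuse_classes()[[cl]]]
    expect_true(all(onclass == 0, na.rm = TRUE))
  }
  # a class with a configured total but no cells is an error
  totals2 <- totals * 0
  totals2[["forest"]] <- 1
  expect_error(deposition_by_landuse(ix, lu, totals2), "no such cells")
})

test_that("column series survive the plain-text round trip", {
  set.seed(13)
  fields <- array(runif(3 * 4 * 5), c(3, 4, 5))
  valid <- array(runif(60) < 0.8, c(3, 4, 5))
  s <- column_series("NH3", fields, valid, cellsize = 8000)
  base <- tempfile()
  write_column_series(s, base)
  s2 <- read_column_series(base)
  expect_identical(s2$fields, s$fields)
  expect_identical(s2$valid, s$valid)
  expect_equal(s2$cellsize, 8000)
  expect_identical(monthly_mean(s2)$values, monthly_mean(s)$values)
})
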