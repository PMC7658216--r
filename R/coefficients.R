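#' Default coefficient library
#'
#' All rate parameters of the budget in one nested list: animal excretion
#' factors and manure return rates (per receiving land use), human excretion
#' and return rates, biological-fixation rates, nationally uniform per-area
#' rates, surface-water runoff coefficients, wastewater per-capita / per-GDP
#' coefficients, and per-class national deposition totals.
#'
#' Every value is config-supplied; the defaults shipped here are illustrative
#' order-of-magnitude choices documented in the methods vignette (the
#' underlying accounting protocols publish no single canonical set). Units:
#' excretion factors kg N/head/yr or kg N/person/yr; return rates and runoff
#' coefficients dimensionless fractions; fixation and uniform rates
#' kg N/ha/yr; wastewater coefficients kg N/person/yr; industrial intensity
#' kg N per GDP currency unit; deposition totals kg N/yr.
#'
#' @return A `coefficient_library` (named list).
#' @export
default_coefficients <- function() {
  coeffs <- list(
    excre_an = c(pigs = 8, cattle = 40, sheep = 8, poultry = 0.5),
    re_an = list(
      cropland  = c(pigs = 0.30, cattle = 0.30, sheep = 0.20, poultry = 0.40),
      grassland = c(pigs = 0.00, cattle = 0.15, sheep = 0.25, poultry = 0.00)
    ),
    excre_hu = 4.0,
    re_ur = 0.10,
    re_ru = 0.40,
    r_fix = list(
      crops = c(rice = 20, wheat = 10, maize = 10, soybean = 80),
      forest = 8,
      grassland = 4
    ),
    uniform_rates = c(
      "straw recycle" = 15,
      "irrigation" = 5,
      "irrigation for artificial grassland" = 0.5
    ),
    runoff_coeffs = c(cropland = 0.05, livestock = 0.11, forest = 0.11),
    wastewater_per_capita = 1.4,
    wtp_effluent_per_capita = 1.5,
    industrial_n_per_gdp = 3e-5,
    deposition_totals = c(
      "cropland" = 5.9e9, "forest" = 5.5e9, "grassland" = 3.5e9,
      "water" = 0.6e9, "built-up" = 1.0e9, "unused" = 1.6e9
    ),
    deposition_index_weights = c(no2 = 0.5, nh3 = 0.5)
  )
  validate_coefficients(coeffs)
}

#' Validate a coefficient library
#'
#' Fractions must lie in [0, 1], rates must be non-negative, and the animal
#' categories of the return-rate vectors must match the excretion factors.
#'
#' @param coeffs Named list as produced by [default_coefficients()].
#' @return The library, classed `coefficient_library`, or an error.
#' @export
validate_coefficients <- function(coeffs) {
  frac_ok <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  rate_ok <- function(x) all(is.finite(x)) && all(x >= 0)
  if (!rate_ok(coeffs$excre_an))
    stop("excre_an must be non-negative", call. = FALSE)
  for (lu in names(coeffs$re_an)) {
    if (!frac_ok(coeffs$re_an[[lu]]))
      stop("re_an[", lu, "] fractions must be in [0,1]", call. = FALSE)
    gap <- setdiff(names(coeffs$excre_an), names(coeffs$re_an[[lu]]))
    if (length(gap))
      stop("re_an[", lu, "] missing categories: ",
           paste(gap, collapse = ", "), call. = FALSE)
  }
  if (!frac_ok(c(coeffs$re_ur, coeffs$re_ru)))
    stop("re_ur / re_ru must be fractions in [0,1]", call. = FALSE)
  if (!rate_ok(coeffs$excre_hu))
    stop("excre_hu must be non-negative", call. = FALSE)
  if (!rate_ok(unlist(coeffs$r_fix)))
    stop("r_fix rates must be non-negative", call. = FALSE)
  if (!rate_ok(coeffs$uniform_rates))
    stop("uniform rates must be non-negative", call. = FALSE)
  if (!frac_ok(coeffs$runoff_coeffs))
    stop("runoff coefficients must be fractions in [0,1]", call. = FALSE)
  if (!rate_ok(c(coeffs$wastewater_per_capita, coeffs$wtp_effluent_per_capita,
                 coeffs$industrial_n_per_gdp)))
    stop("wastewater coefficients must be non-negative", call. = FALSE)
  if (!rate_ok(coeffs$deposition_totals) ||
      !setequal(names(coeffs$deposition_totals), names(landuse_classes())))
    stop("deposition_totals must be non-negative and cover all six classes",
         call. = FALSE)
  class(coeffs) <- c("coefficient_library", "list")
  coeffs
}

#' Read / write a coefficient library as YAML
#'
#' @param coeffs Coefficient library.
#' @param path YAML file path.
#' @return `read_coefficients` returns a validated library; `write_coefficients`
#'   returns `path` invisibly.
#' @export
write_coefficients <- function(coeffs, path) {
  # named atomic vectors must become maps, or YAML drops the names
  listify <- function(x) {
    if (is.list(x)) lapply(x, listify)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(listify(unclass(coeffs)), path, precision = 17)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  x <- yaml::read_yaml(path)
  # yaml round-trips named vectors as lists; restore numeric vectors
  to_num <- function(l) if (is.list(l)) unlist(l) else l
  for (k in c("excre_an", "uniform_rates", "runoff_coeffs",
              "deposition_totals", "deposition_index_weights"))
    x[[k]] <- to_num(x[[k]])
  x$re_an <- lapply(x$re_an, to_num)
  x$r_fix$crops <- to_num(x$r_fix$crops)
  x$r_fix$forest <- as.numeric(x$r_fix$forest)
  x$r_fix$grassland <- as.numeric(x$r_fix$grassland)
  validate_coefficients(x)
}
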