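#' Mass-conserving dasymetric allocation of regional totals onto the grid
#'
#' Distributes each region's flux magnitude over its grid cells in
#' proportion to a non-negative proxy surface, restricted to an eligibility
#' mask. Within each region the output cells sum to the regional total
#' exactly (one floating-point normalization per region), so zonal
#' re-aggregation is the identity on regional totals, and the allocation is
#' invariant to rescaling the proxy by a positive constant.
#'
#' Fallback policy when a region has nonzero flux: if its eligible proxy
#' sums to zero, the flux is spread uniformly over the eligible cells; if
#' the region has no eligible cells at all, uniformly over all cells of the
#' region, with a warning naming the region.
#'
#' @param flux_by_region Named numeric vector: region raster code (as
#'   character) -> kg N/yr. Regions absent from the vector allocate nothing.
#' @param region_raster `grid_map` of integer region codes (NA = outside
#'   the domain).
#' @param proxy `grid_map` of non-negative proxy weights (NA treated as 0).
#' @param eligible_mask Optional `grid_map`; cells with value > 0 are
#'   eligible. Default: all domain cells eligible.
#' @return `grid_map` in kg N/cell: 0 on domain cells receiving nothing,
#'   NA outside the domain.
#' @export
allocate <- function(flux_by_region, region_raster, proxy,
                     eligible_mask = NULL) {
  stop_if_incompatible(region_raster, proxy, "region and proxy grids")
  if (!is.null(eligible_mask))
    stop_if_incompatible(region_raster, eligible_mask,
                         "region and mask grids")
  pv <- proxy$values
  pv[is.na(pv)] <- 0
  if (any(pv < 0))
    stop("proxy surface must be non-negative", call. = FALSE)
  rz <- region_raster$values
  elig <- if (is.null(eligible_mask)) !is.na(rz) else
    !is.na(eligible_mask$values) & eligible_mask$values > 0 & !is.na(rz)

  out <- matrix(0, nrow(rz), ncol(rz))
  out[is.na(rz)] <- NA_real_
  for (code in names(flux_by_region)) {
    total <- flux_by_region[[code]]
    if (total == 0) next
    in_region <- !is.na(rz) & rz == as.numeric(code)
    cells <- in_region & elig
    if (!any(cells)) {
      if (!any(in_region))
        stop("region code ", code, " has flux but no raster cells",
             call. = FALSE)
      warning("region ", code,
              ": no eligible cells; allocating uniformly over the region",
              call. = FALSE)
      cells <- in_region
      w <- rep(1, sum(cells))
    } else {
      w <- pv[cells]
      if (sum(w) == 0) w <- rep(1, length(w))  # zero-proxy fallback
    }
    out[cells] <- out[cells] + total * (w / sum(w))
  }
  res <- region_raster
  res$values <- out
  res
}

#' Allocate every regional flux of one (land use, item) onto the grid
#'
#' Convenience wrapper: pulls the regional rows of `tab` for one
#' (landuse, item), maps `region_id` to raster codes via the AdminSet, and
#' calls [allocate()].
#'
#' @param tab Flux table with regional rows.
#' @param landuse,item The flux to map.
#' @param regions AdminSet (county rows carry `raster_code`).
#' @param region_raster,proxy,eligible_mask As in [allocate()].
#' @return `grid_map` in kg N/cell.
#' @export
allocate_item <- function(tab, landuse, item, regions, region_raster,
                          proxy, eligible_mask = NULL) {
  counties <- admin_counties(regions)
  rows <- tab[tab$region_id != "national" & tab$landuse == landuse &
                tab$item == item, , drop = FALSE]
  codes <- counties$raster_code[match(rows$region_id, counties$region_id)]
  if (any(is.na(codes)))
    stop("regional rows reference regions without raster codes",
         call. = FALSE)
  allocate(stats::setNames(rows$kgN_per_yr, as.character(codes)),
           region_raster, proxy, eligible_mask)
}

#' Uniform proxy (all ones) on a template grid
#' @param template `grid_map` supplying shape and georeference.
#' @return `grid_map` of ones (NA preserved from template).
#' @export
uniform_proxy <- function(template) {
  out <- template
  v <- matrix(1, nrow(template$values), ncol(template$values))
  v[is.na(template$values)] <- NA_real_
  out$values <- v
  out
}

#' Binary mask of a land-use class
#' @param landuse_raster `grid_map` of class codes.
#' @param class Land-use class name.
#' @return `grid_map`: 1 where the cell is of the class, 0 elsewhere,
#'   NA outside the domain.
#' @export
landuse_mask <- function(landuse_raster, class) {
  code <- landuse_classes()[[class]]
  out <- landuse_raster
  v <- ifelse(landuse_raster$values == code, 1, 0)
  out$values <- v
  out
}
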