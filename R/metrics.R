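# Range statistics: extent of occurrence (minimum convex polygon area),
# area of occupancy (occupancy-grid cell count x cell area), unique record
# count, and occupied Level-3 region count. Areas are computed in km^2 on a
# cylindrical equal-area projection fitted per species to its own points, so
# the km^2 figures are latitude-honest without a global projection choice.

EARTH_RADIUS_KM <- 6371.0088  # IUGG mean radius

#' Fit a per-species equal-area projection context
#'
#' Cylindrical equal-area projection with the central meridian at the points'
#' mean longitude and the standard parallel at their mean latitude, so
#' distortion is minimal where the species actually occurs. Recomputed per
#' species from its own points.
#'
#' @param points A [filtered_occurrences()] result, an [occurrence_set()], or
#'   a data frame with `longitude` and `latitude` columns.
#' @return A `projection_context` with `central_meridian` and
#'   `standard_parallel` in degrees.
#' @export
projection_context <- function(points) {
  rec <- as_point_table(points)
  if (nrow(rec) == 0L) {
    ctx <- list(central_meridian = 0, standard_parallel = 0)
  } else {
    ctx <- list(
      central_meridian = mean(rec$longitude),
      standard_parallel = mean(rec$latitude)
    )
  }
  structure(ctx, class = "projection_context")
}

as_point_table <- function(points) {
  if (inherits(points, "filtered_occurrences")) points <- points$retained
  if (inherits(points, "occurrence_set")) return(points$records)
  tibble::as_tibble(points)
}

#' Project lon/lat points to equal-area kilometre coordinates
#'
#' @param points Anything accepted by [projection_context()].
#' @param ctx A [projection_context()]; fitted from `points` when omitted.
#' @return A tibble with `x` and `y` in km.
#' @export
project_points <- function(points, ctx = projection_context(points)) {
  rec <- as_point_table(points)
  lam0 <- ctx$central_meridian * pi / 180
  phi1 <- ctx$standard_parallel * pi / 180
  lam <- rec$longitude * pi / 180
  phi <- rec$latitude * pi / 180
  # y is offset so the projection origin sits at (central meridian,
  # standard parallel); the shift is area-preserving and keeps the origin —
  # and hence the AOO grid anchor — at the species' own centroid
  tibble::tibble(
    x = EARTH_RADIUS_KM * (lam - lam0) * cos(phi1),
    y = EARTH_RADIUS_KM * (sin(phi) - sin(phi1)) / cos(phi1)
  )
}

# Shoelace area of a polygon given in vertex order.
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Extent of occurrence (EOO)
#'
#' Area in km^2 of the minimum convex polygon of all retained occurrence
#' points, on the equal-area projection. Fewer than three distinct points, or
#' collinear points, yield a degenerate hull: EOO is reported as 0 with a
#' warning message (a warning, never an error).
#'
#' @param points A [filtered_occurrences()], [occurrence_set()] or point
#'   table.
#' @param ctx A [projection_context()].
#' @return A number (km^2) with attribute `warning` ("" when clean).
#' @export
compute_eoo <- function(points, ctx = projection_context(points)) {
  xy <- unique(project_points(points, ctx))
  if (nrow(xy) < 3L) {
    return(structure(0, warning = "fewer than 3 distinct points; EOO set to 0"))
  }
  hull <- grDevices::chull(xy$x, xy$y)
  if (length(hull) < 3L) {
    return(structure(0, warning = "points are collinear; EOO set to 0"))
  }
  area <- shoelace_area(xy$x[hull], xy$y[hull])
  # degeneracy guard: collinear inputs can leave a sliver of floating-point
  # area after projection; anything below 1e-12 of the squared extent is a
  # line, not a polygon
  extent2 <- (max(xy$x) - min(xy$x))^2 + (max(xy$y) - min(xy$y))^2
  if (area <= 1e-12 * max(extent2, 1)) {
    return(structure(0, warning = "points are collinear; EOO set to 0"))
  }
  structure(area, warning = "")
}

#' Area of occupancy (AOO) on an occupancy grid
#'
#' Counts occupied grid cells of side `cell_km` (default 10 km — coarser than
#' the 2 km IUCN reference scale, to absorb georeference error) and returns
#' occupied cells times cell area. The grid is anchored at the projection
#' origin with a cell centred on it; no origin optimisation is performed, so
#' a given projection context always yields the same cells. Because the
#' per-species projection puts the origin at the points' centroid, centring
#' a cell there (rather than a cell corner) means a cluster much smaller
#' than the cell occupies a single cell: at the default scale it returns
#' 100 km^2.
#'
#' @inheritParams compute_eoo
#' @param cell_km Grid cell side in km, > 0.
#' @return A number (km^2), a multiple of `cell_km^2`.
#' @export
compute_aoo <- function(points, ctx = projection_context(points),
                        cell_km = 10) {
  stopifnot(is_scalar_number(cell_km), cell_km > 0)
  xy <- project_points(points, ctx)
  if (nrow(xy) == 0L) {
    return(structure(0, warning = "no points; AOO set to 0"))
  }
  cells <- unique(paste(floor(xy$x / cell_km + 0.5),
                        floor(xy$y / cell_km + 0.5)))
  structure(length(cells) * cell_km^2, warning = "")
}

#' Number of unique georeferenced records
#'
#' @inheritParams compute_eoo
#' @return Count of unique (longitude, latitude) pairs retained.
#' @export
count_records <- function(points) {
  rec <- as_point_table(points)
  nrow(unique(rec[, c("longitude", "latitude")]))
}

#' Number of occupied Level-3 regions
#'
#' Counts the native WGSRPD Level-3 regions in which the species actually
#' occurs (regions with at least one retained point), as computed by
#' [filter_to_native()].
#'
#' @param points A [filtered_occurrences()] result.
#' @return `length(points$regions_hit)`.
#' @export
count_tdwg <- function(points) {
  stopifnot(inherits(points, "filtered_occurrences"))
  length(points$regions_hit)
}

#' Compute all four range statistics
#'
#' Composes [compute_eoo()], [compute_aoo()], [count_records()] and
#' [count_tdwg()] into one metrics row. When the species has no retained
#' georeferenced points, all metrics are zero and the warning column explains
#' why, so the species is reported rather than silently dropped.
#'
#' @param points A [filtered_occurrences()] result.
#' @param ctx A [projection_context()]; refitted from the retained points
#'   when omitted.
#' @param cell_km AOO grid cell side in km.
#' @return A `range_metrics` object: a one-row tibble with columns
#'   `eoo_km2`, `aoo_km2`, `record_count`, `tdwg_count`, `warning`.
#' @export
compute_metrics <- function(points, ctx = projection_context(points),
                            cell_km = 10) {
  stopifnot(inherits(points, "filtered_occurrences"))
  n <- count_records(points)
  if (n == 0L) {
    out <- tibble::tibble(
      eoo_km2 = 0, aoo_km2 = 0, record_count = 0L, tdwg_count = 0L,
      warning = "no georeferenced points within the native range to carry out the area calculations"
    )
    class(out) <- c("range_metrics", class(out))
    return(out)
  }
  eoo <- compute_eoo(points, ctx)
  aoo <- compute_aoo(points, ctx, cell_km)
  warnings <- c(attr(eoo, "warning"), attr(aoo, "warning"))
  warnings <- warnings[nzchar(warnings)]
  out <- tibble::tibble(
    eoo_km2 = as.numeric(eoo),
    aoo_km2 = as.numeric(aoo),
    record_count = n,
    tdwg_count = count_tdwg(points),
    warning = paste(warnings, collapse = "; ")
  )
  class(out) <- c("range_metrics", class(out))
  out
}
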