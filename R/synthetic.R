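# Synthetic test-input generators: clustered occurrence clouds, toy
# rectangular Level-3 region grids, canned backend documents and validation
# tables with planted class structure. Everything is deterministic under a
# seed, so every module is testable fully offline.

#' Generate a clustered occurrence cloud
#'
#' Draws `n` points from an isotropic Gaussian of standard deviation
#' `dispersion_km` (in projected km, so the spatial spread is
#' latitude-independent) around a centroid, and back-projects them to
#' longitude/latitude.
#'
#' @param centroid_lon,centroid_lat Cloud centre in degrees.
#' @param dispersion_km Isotropic standard deviation in km.
#' @param n Number of points (>= 0).
#' @param seed Integer seed; the same seed always yields the identical
#'   cloud.
#' @param taxon_ref Label for the resulting occurrence set.
#' @return An [occurrence_set()].
#' @export
gen_cloud <- function(centroid_lon, centroid_lat, dispersion_km = 1,
                      n = 5L, seed = 1L, taxon_ref = "synthetic") {
  stopifnot(n >= 0)
  withr::local_seed(seed)
  dx <- stats::rnorm(n, 0, dispersion_km)
  dy <- stats::rnorm(n, 0, dispersion_km)
  phi1 <- centroid_lat * pi / 180
  lon <- centroid_lon + dx / (EARTH_RADIUS_KM * cos(phi1)) * 180 / pi
  # invert y = R sin(phi) / cos(phi1) about the centroid
  y0 <- EARTH_RADIUS_KM * sin(phi1) / cos(phi1)
  lat <- asin(pmin(1, pmax(-1, (y0 + dy) * cos(phi1) / EARTH_RADIUS_KM))) *
    180 / pi
  occurrence_set(
    tibble::tibble(longitude = lon, latitude = lat),
    taxon_ref = taxon_ref,
    requested_limit = max(n, 1L)
  )
}

#' Generate a toy rectangular region grid
#'
#' Lays out `n` non-overlapping rectangular Level-3 regions in a row, coded
#' `AAA`, `AAB`, ... Useful as a geometry store for offline tests.
#'
#' @param n Number of regions.
#' @param origin_lon,origin_lat Lower-left corner of the first rectangle.
#' @param width,height Rectangle size in degrees.
#' @param gap Horizontal gap between rectangles in degrees (0 = shared
#'   borders).
#' @return A [region_store()]; region codes are in `names()` order.
#' @export
gen_toy_regions <- function(n = 3L, origin_lon = 0, origin_lat = 0,
                            width = 10, height = 10, gap = 0) {
  stopifnot(n >= 1L, n <= 26L^2)
  codes <- vapply(seq_len(n) - 1L, function(i) {
    paste0("A", LETTERS[i %/% 26L + 1L], LETTERS[i %% 26L + 1L])
  }, character(1))
  regions <- lapply(seq_len(n) - 1L, function(i) {
    x0 <- origin_lon + i * (width + gap)
    list(rect_ring(x0, origin_lat, x0 + width, origin_lat + height))
  })
  names(regions) <- codes
  region_store(regions)
}

rect_ring <- function(x0, y0, x1, y1) {
  matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), ncol = 2, byrow = TRUE)
}

#' Generate a validation table with planted class structure
#'
#' Stands in for a published-assessment validation set: Least Concern
#' species draw stochastically larger range metrics than threatened ones
#' (log-normal metrics, threatened means scaled down by the effect size),
#' with optional planted wide-ranging threatened outliers whose metrics are
#' drawn from the LC distribution — the pattern of a widespread species
#' threatened by range-wide exploitation, which no range-based threshold can
#' separate.
#'
#' @param n_lc,n_threatened Class sizes (>= 0).
#' @param effect_size Ratio of LC to threatened median metrics (> 1 plants
#'   separation).
#' @param n_outliers Number of threatened species drawn from the LC metric
#'   distribution.
#' @param seed Integer seed.
#' @return A tibble usable with [validation_records()]: columns `name`,
#'   `category`, `eoo_km2`, `aoo_km2`, `record_count`, `tdwg_count`.
#' @export
gen_validation_table <- function(n_lc = 100L, n_threatened = 100L,
                                 effect_size = 20, n_outliers = 0L,
                                 seed = 1L) {
  stopifnot(n_lc >= 0, n_threatened >= 0, n_outliers >= 0,
            n_outliers <= n_threatened, effect_size > 0)
  withr::local_seed(seed)
  draw <- function(n, scale) {
    # medians chosen so LC species at scale=1 sit comfortably above the
    # default thresholds and threatened species (scale = 1/effect_size) below
    tibble::tibble(
      eoo_km2 = stats::rlnorm(n, log(60000 * scale), 0.6),
      aoo_km2 = stats::rlnorm(n, log(6000 * scale), 0.6),
      record_count = round(stats::rlnorm(n, log(150 * scale), 0.6)),
      tdwg_count = pmax(1, round(stats::rlnorm(n, log(10 * scale), 0.5)))
    )
  }
  lc <- draw(n_lc, 1)
  lc$category <- "LC"
  th <- draw(n_threatened - n_outliers, 1 / effect_size)
  th$category <- sample(c("VU", "EN", "CR", "NT"),
                        nrow(th), replace = TRUE)
  out <- draw(n_outliers, 1)
  out$category <- rep("VU", n_outliers)
  tbl <- dplyr::bind_rows(lc, th, out)
  tbl$name <- sprintf("Synthetica species%03d", seq_len(nrow(tbl)))
  tbl[, c("name", "category", "eoo_km2", "aoo_km2", "record_count",
          "tdwg_count")]
}

#' Write fixture backend documents
#'
#' Emits the canned JSON documents the fixture backends read
#' ([read_name_backbone()], [read_range_provider()],
#' [read_occurrence_backend()]) plus a GeoJSON region store, in the same
#' dialects the ingest functions consume.
#'
#' @param dir Output directory.
#' @param backbone,ranges,occurrences Tables as taken by [name_backbone()],
#'   [range_provider()] and [occurrence_backend()].
#' @param store A [region_store()].
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture_backends <- function(dir, backbone, ranges, occurrences,
                                   store) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    backbone = file.path(dir, "name_backbone.json"),
    ranges = file.path(dir, "native_ranges.json"),
    occurrences = file.path(dir, "occurrences.json"),
    regions = file.path(dir, "regions.geojson")
  )
  jsonlite::write_json(backbone, paths[["backbone"]], dataframe = "rows",
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  jsonlite::write_json(ranges, paths[["ranges"]], dataframe = "rows",
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(occurrences, paths[["occurrences"]],
                       dataframe = "rows", digits = NA, pretty = TRUE)
  write_region_geojson(store, paths[["regions"]])
  invisible(paths)
}

#' Write a region store as GeoJSON
#'
#' @param store A [region_store()].
#' @param path Output `.geojson` path; one FeatureCollection, one feature
#'   per region, code in the `LEVEL3_COD` property.
#' @return Invisibly, `path`.
#' @export
write_region_geojson <- function(store, path) {
  features <- lapply(names(store$regions), function(code) {
    rings <- store$regions[[code]]
    polys <- lapply(rings, function(r) {
      closed <- rbind(r, r[1, , drop = FALSE])
      list(lapply(seq_len(nrow(closed)), function(i) {
        c(closed[i, 1], closed[i, 2])
      }))
    })
    list(
      type = "Feature",
      properties = list(LEVEL3_COD = code),
      geometry = list(type = "MultiPolygon", coordinates = polys)
    )
  })
  doc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
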