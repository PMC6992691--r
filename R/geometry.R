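# WGSRPD Level-3 region geometries and point-in-polygon filtering.
#
# Geometries are kept as plain lists of rings (two-column lon/lat matrices)
# keyed by L3 code. Filtering is geographic (unprojected), treating degrees
# as planar: WGSRPD units are large relative to any projection distortion,
# and the store contract requires polygons crossing the antimeridian to be
# pre-split into two lobes so longitudes stay in [-180, 180].

#' Build a region geometry store from rings
#'
#' @param regions A named list: for each L3 code, a list of rings, each ring
#'   a two-column matrix of (longitude, latitude) vertices. Rings need not
#'   repeat the first vertex; they are closed implicitly.
#' @return A `region_store` object mapping codes to multi-polygons.
#' @export
region_store <- function(regions) {
  stopifnot(is.list(regions), !is.null(names(regions)),
            !anyDuplicated(names(regions)))
  regions <- lapply(regions, function(rings) {
    lapply(rings, function(r) {
      r <- as.matrix(r)
      stopifnot(ncol(r) == 2, nrow(r) >= 3)
      # drop an explicit closing vertex; closure is implicit
      if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
      unname(r)
    })
  })
  names(regions) <- toupper(names(regions))
  structure(list(regions = regions), class = "region_store")
}

#' @export
print.region_store <- function(x, ...) {
  cat("<region_store> ", length(x$regions), " regions: ",
      paste(utils::head(names(x$regions), 10), collapse = " "),
      if (length(x$regions) > 10) " ...", "\n", sep = "")
  invisible(x)
}

#' Read a region store from GeoJSON
#'
#' Reads one or more GeoJSON FeatureCollections (Polygon or MultiPolygon
#' features) whose features carry the Level-3 code in the `LEVEL3_COD`
#' property, the convention used by published WGSRPD geometry distributions.
#'
#' @param path A `.geojson`/`.json` file or a directory of them.
#' @param code_property Feature property holding the L3 code.
#' @return A [region_store()].
#' @export
read_region_store <- function(path, code_property = "LEVEL3_COD") {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.(geo)?json$", full.names = TRUE)
  } else path
  regions <- list()
  for (f in files) {
    doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
    feats <- if (identical(doc$type, "FeatureCollection")) doc$features
             else list(doc)
    for (feat in feats) {
      code <- feat$properties[[code_property]]
      if (is.null(code)) next
      geom <- feat$geometry
      coords <- geom$coordinates
      polys <- switch(geom$type,
        Polygon = list(coords),
        MultiPolygon = coords,
        stop("unsupported geometry type: ", geom$type)
      )
      rings <- list()
      for (poly in polys) {
        # outer ring only; WGSRPD units are effectively hole-free at L3
        ring <- poly[[1]]
        m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
        rings <- c(rings, list(m))
      }
      regions[[toupper(code)]] <- rings
    }
  }
  region_store(regions)
}

# Point-on-segment test: is p on the closed segment a-b (planar)?
on_segment <- function(px, py, ax, ay, bx, by, eps = 1e-12) {
  cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
  scale <- pmax(abs(bx - ax), abs(by - ay), 1)
  within <- px >= pmin(ax, bx) - eps & px <= pmax(ax, bx) + eps &
    py >= pmin(ay, by) - eps & py <= pmax(ay, by) + eps
  abs(cross) <= eps * scale & within
}

# Winding-number point-in-polygon over one ring, vectorised over points.
# Boundary vertices and edge points count as inside (precautionary: a record
# on a region border must not shrink the range metrics).
points_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  wn <- integer(length(px))
  boundary <- logical(length(px))
  for (i in seq_len(n)) {
    ax <- ring[i, 1]; ay <- ring[i, 2]
    j <- if (i == n) 1L else i + 1L
    bx <- ring[j, 1]; by <- ring[j, 2]
    boundary <- boundary | on_segment(px, py, ax, ay, bx, by)
    upward <- ay <= py & by > py
    downward <- ay > py & by <= py
    is_left <- (bx - ax) * (py - ay) - (px - ax) * (by - ay)
    wn <- wn + ifelse(upward & is_left > 0, 1L,
                      ifelse(downward & is_left < 0, -1L, 0L))
  }
  wn != 0L | boundary
}

points_in_region <- function(px, py, rings) {
  inside <- logical(length(px))
  for (ring in rings) inside <- inside | points_in_ring(px, py, ring)
  inside
}

#' Restrict occurrences to the taxon's native range
#'
#' Performs the spatial query at the heart of the screening pipeline: a
#' record is retained iff it lies inside, or exactly on the boundary of, at
#' least one polygon of a native Level-3 region. All non-native records
#' (including those in introduced-only regions) are excluded from any further
#' analysis.
#'
#' @param set An [occurrence_set()] (cleaned).
#' @param range A [native_range()].
#' @param store A [region_store()] resolving every native code.
#' @return A `filtered_occurrences` object: `retained` (an occurrence set),
#'   `removed_count`, and `regions_hit` (native codes with at least one
#'   retained point).
#' @export
filter_to_native <- function(set, range, store) {
  stopifnot(inherits(set, "occurrence_set"), inherits(range, "native_range"),
            inherits(store, "region_store"))
  codes <- range$native_codes
  missing <- setdiff(codes, names(store$regions))
  if (length(missing)) {
    abort_config(paste0(
      "no geometry in store for native code(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  rec <- set$records
  n <- nrow(rec)
  if (n == 0L) {
    return(structure(
      list(retained = set, removed_count = 0L, regions_hit = character()),
      class = "filtered_occurrences"
    ))
  }
  if (length(codes) == 0L) {
    warn("taxon has no native region codes; all occurrence records removed.")
    empty <- occurrence_set(rec[0, , drop = FALSE], taxon_ref = set$taxon_ref,
                            truncated = set$truncated,
                            requested_limit = set$requested_limit)
    return(structure(
      list(retained = empty, removed_count = n, regions_hit = character()),
      class = "filtered_occurrences"
    ))
  }
  membership <- vapply(codes, function(code) {
    points_in_region(rec$longitude, rec$latitude, store$regions[[code]])
  }, logical(n))
  membership <- matrix(membership, nrow = n,
                       dimnames = list(NULL, codes))
  keep <- rowSums(membership) > 0
  retained <- occurrence_set(
    rec[keep, , drop = FALSE], taxon_ref = set$taxon_ref,
    truncated = set$truncated, requested_limit = set$requested_limit
  )
  structure(
    list(
      retained = retained,
      removed_count = as.integer(n - sum(keep)),
      regions_hit = codes[colSums(membership[keep, , drop = FALSE]) > 0]
    ),
    class = "filtered_occurrences"
  )
}

#' @export
print.filtered_occurrences <- function(x, ...) {
  cat("<filtered_occurrences> retained ", nrow(x$retained$records),
      ", removed ", x$removed_count, "; regions hit: ",
      paste(x$regions_hit, collapse = " "), "\n", sep = "")
  invisible(x)
}
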