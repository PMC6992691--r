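# In-code fixture backends shared across tests.

toy_backbone <- function() {
  name_backbone(tibble::tibble(
    canonical_name = c("Aloe zebrina", "Aloe platyphylla", "Poa annua"),
    authorship = c("Baker", "Baker", "L."),
    family = c("Asphodelaceae", "Asphodelaceae", "Poaceae"),
    usage_key = c("k1", "k2", "k3"),
    is_synonym = c(FALSE, TRUE, FALSE),
    accepted_name = c("Aloe zebrina", "Aloe zebrina", "Poa annua")
  ))
}

toy_provider <- function() {
  range_provider(tibble::tibble(
    usage_key = c("k1", "k3"),
    powo_id = c("p1", "p3"),
    native_codes = list(c("AAA", "AAB"), "AAC"),
    introduced_codes = list("AAC", character())
  ))
}

# Occurrence backend over the 3-region toy grid of gen_toy_regions():
# AAA = [0,10]x[0,10], AAB = [10,20]x[0,10], AAC = [20,30]x[0,10].
toy_occ_backend <- function() {
  occurrence_backend(tibble::tibble(
    usage_key = c(rep("k1", 6), "k3"),
    decimalLongitude = c(2, 5, 12, 25, NA, 3, 25),
    decimalLatitude = c(2, 5, 5, 5, 4, 3, 5),
    source_id = sprintf("s%d", 1:7),
    hasGeospatialIssue = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  ))
}

failing_backend <- function() {
  list(match = function(...) transport_error("service down"),
       lookup = function(...) transport_error("service down"),
       search = function(...) transport_error("service down"))
}

points_set <- function(lon, lat, ...) {
  occurrence_set(tibble::tibble(longitude = lon, latitude = lat), ...)
}

square_store <- function() {
  region_store(list(NAT = list(rect_ring_mat(0, 0, 10, 10)),
                    INT = list(rect_ring_mat(20, 0, 30, 10))))
}

rect_ring_mat <- function(x0, y0, x1, y1) {
  matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), ncol = 2, byrow = TRUE)
}

# Inverse of the package's equal-area projection for a given context, used
# to construct lon/lat preimages of prescribed projected km coordinates.
unproject_points <- function(x, y, ctx) {
  phi1 <- ctx$standard_parallel * pi / 180
  lon <- ctx$central_meridian + x / (6371.0088 * cos(phi1)) * 180 / pi
  lat <- asin(pmin(1, pmax(-1, y * cos(phi1) / 6371.0088 + sin(phi1)))) *
    180 / pi
  tibble::tibble(longitude = lon, latitude = lat)
}

flat_ctx <- structure(list(central_meridian = 0, standard_parallel = 0),
                      class = "projection_context")

as_filtered <- function(set, regions_hit = character()) {
  structure(list(retained = set, removed_count = 0L,
                 regions_hit = regions_hit),
            class = "filtered_occurrences")
}
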