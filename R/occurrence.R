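#' Construct an occurrence set
#'
#' @param records A data frame with columns `longitude`, `latitude`,
#'   `source_id`, `has_geospatial_issue` (missing metadata columns are
#'   filled).
#' @param taxon_ref Usage key or input name the records belong to.
#' @param truncated Whether the backend held more records than retained.
#' @param requested_limit The record limit in force when fetched.
#' @return An `occurrence_set` object.
#' @export
occurrence_set <- function(records, taxon_ref = NA_character_,
                           truncated = FALSE, requested_limit = 3000L) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L && ncol(records) == 0L) {
    records <- tibble::tibble(longitude = numeric(), latitude = numeric())
  }
  stopifnot(all(c("longitude", "latitude") %in% names(records)))
  if (!"source_id" %in% names(records)) {
    records$source_id <- as.character(seq_len(nrow(records)))
  }
  if (!"has_geospatial_issue" %in% names(records)) {
    records$has_geospatial_issue <- FALSE
  }
  stopifnot(nrow(records) <= requested_limit)
  structure(
    list(
      taxon_ref = taxon_ref,
      records = records[, c("longitude", "latitude", "source_id",
                            "has_geospatial_issue")],
      truncated = isTRUE(truncated),
      requested_limit = as.integer(requested_limit)
    ),
    class = "occurrence_set"
  )
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat("<occurrence_set> ", x$taxon_ref, ": ", nrow(x$records), " records",
      if (x$truncated) paste0(" (truncated at ", x$requested_limit, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Fetch occurrence records from a backend
#'
#' Retrieves the taxon's georeferenced, issue-free occurrence records, in the
#' backend's stable order, truncated at `limit`. The limit mirrors the
#' occurrence-service slider: between 1,000 and 10,000 records, default
#' 3,000.
#'
#' @param usage_key Backbone identifier of the taxon.
#' @param backend An occurrence backend, e.g. [occurrence_backend()].
#' @param limit Maximum number of records to retain (1000-10000).
#' @return An [occurrence_set()] with `truncated = TRUE` when the backend
#'   reported more records than retained.
#' @export
fetch_occurrences <- function(usage_key, backend, limit = 3000L) {
  if (!is_scalar_number(limit) || limit < 1000 || limit > 10000) {
    abort_config(
      "`limit` must be between 1,000 and 10,000 occurrences (default 3,000)."
    )
  }
  limit <- as.integer(limit)
  res <- backend$search(usage_key, limit)
  rec <- tibble::tibble(
    longitude = as.numeric(res$records$decimalLongitude %||% numeric()),
    latitude = as.numeric(res$records$decimalLatitude %||% numeric()),
    source_id = as.character(res$records$source_id %||% character()),
    has_geospatial_issue = FALSE
  )
  occurrence_set(rec, taxon_ref = as.character(usage_key),
                 truncated = res$total > nrow(rec), requested_limit = limit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load user-supplied occurrence records from CSV
#'
#' Reads a CSV of `name`, `decimalLatitude`, `decimalLongitude` rows (header
#' names configurable), groups rows by name, drops rows whose coordinates do
#' not parse, and bypasses the occurrence backend entirely.
#'
#' @param path CSV file path (comma-delimited, UTF-8, header row).
#' @param name_col,lat_col,lon_col Header names of the three required
#'   columns.
#' @return A named list of [occurrence_set()] (one per name, in first-seen
#'   order), with attribute `dropped` giving the per-name count of malformed
#'   coordinate rows.
#' @export
load_user_occurrences <- function(path, name_col = "name",
                                  lat_col = "decimalLatitude",
                                  lon_col = "decimalLongitude") {
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(c(name_col, lat_col, lon_col), names(tbl))
  if (length(missing)) {
    abort_schema(
      paste0("occurrence CSV lacks required columns: ",
             paste(missing, collapse = ", ")),
      missing = missing
    )
  }
  lat <- suppressWarnings(as.numeric(tbl[[lat_col]]))
  lon <- suppressWarnings(as.numeric(tbl[[lon_col]]))
  ok <- !is.na(lat) & !is.na(lon)
  names_all <- tbl[[name_col]]
  order_names <- unique(names_all)
  dropped <- vapply(order_names, function(nm) sum(names_all == nm & !ok),
                    integer(1))
  sets <- lapply(order_names, function(nm) {
    keep <- names_all == nm & ok
    clean_records(occurrence_set(
      tibble::tibble(longitude = lon[keep], latitude = lat[keep]),
      taxon_ref = nm,
      requested_limit = max(sum(keep), 1L)
    ))
  })
  names(sets) <- order_names
  attr(sets, "dropped") <- dropped
  sets
}

#' Clean an occurrence set
#'
#' Applies the coordinate sanity rules used before any range calculation:
#' removes records outside valid longitude/latitude bounds, drops the (0, 0)
#' "null island" sentinel that aggregator data frequently carries, drops
#' records flagged with a geospatial issue, and collapses exact duplicate
#' (longitude, latitude) pairs to their first record. Idempotent; ordering
#' otherwise preserved.
#'
#' @param set An [occurrence_set()].
#' @return A cleaned [occurrence_set()].
#' @export
clean_records <- function(set) {
  stopifnot(inherits(set, "occurrence_set"))
  rec <- set$records
  keep <- rec$longitude >= -180 & rec$longitude <= 180 &
    rec$latitude >= -90 & rec$latitude <= 90 &
    !(rec$longitude == 0 & rec$latitude == 0) &
    !rec$has_geospatial_issue
  keep[is.na(keep)] <- FALSE
  rec <- rec[keep, , drop = FALSE]
  rec <- rec[!duplicated(rec[, c("longitude", "latitude")]), , drop = FALSE]
  occurrence_set(rec, taxon_ref = set$taxon_ref, truncated = set$truncated,
                 requested_limit = set$requested_limit)
}
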