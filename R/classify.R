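#' Least Concern thresholds
#'
#' The default thresholds below which a range statistic is considered
#' compatible with threatened or Near Threatened status. Defaults follow the
#' precautionary calibration against published assessments: EOO 30,000 km^2,
#' AOO 3,000 km^2, 75 unique records, 5 Level-3 regions. All four are
#' user-adjustable per batch.
#'
#' @param eoo_km2,aoo_km2,record_count,tdwg_count Strictly positive
#'   thresholds.
#' @return An `lc_thresholds` object.
#' @export
lc_thresholds <- function(eoo_km2 = 30000, aoo_km2 = 3000,
                          record_count = 75, tdwg_count = 5) {
  vals <- list(eoo_km2 = eoo_km2, aoo_km2 = aoo_km2,
               record_count = record_count, tdwg_count = tdwg_count)
  if (!all(vapply(vals, is_scalar_number, logical(1))) ||
      any(unlist(vals) <= 0)) {
    abort_config("all Least Concern thresholds must be strictly positive numbers.")
  }
  structure(as.list(vals), class = "lc_thresholds")
}

#' @export
print.lc_thresholds <- function(x, ...) {
  cat("<lc_thresholds> EOO >= ", x$eoo_km2, " km2, AOO >= ", x$aoo_km2,
      " km2, records >= ", x$record_count, ", TDWG regions >= ",
      x$tdwg_count, "\n", sep = "")
  invisible(x)
}

#' Evaluate range metrics against Least Concern thresholds
#'
#' Each of the four parameters passes iff the metric meets or exceeds its
#' threshold (inclusive comparison). The species is flagged likely Least
#' Concern iff all four pass and the metrics carry no warning: a warning
#' (e.g. no georeferenced points) means the status is undetermined and is
#' recorded as not-LC with the warning propagated, never as a silent pass.
#'
#' @param metrics A [compute_metrics()] row (or anything with the four
#'   metric columns and a `warning` column).
#' @param thresholds An [lc_thresholds()].
#' @return A `gauge_result`: one-row tibble with the four pass flags,
#'   `least_concern` and `warning`.
#' @export
evaluate <- function(metrics, thresholds = lc_thresholds()) {
  stopifnot(is.data.frame(metrics), nrow(metrics) == 1L)
  warning_txt <- metrics$warning %||% ""
  if (is.na(warning_txt)) warning_txt <- ""
  passes <- tibble::tibble(
    eoo_pass = metrics$eoo_km2 >= thresholds$eoo_km2,
    aoo_pass = metrics$aoo_km2 >= thresholds$aoo_km2,
    records_pass = metrics$record_count >= thresholds$record_count,
    tdwg_pass = metrics$tdwg_count >= thresholds$tdwg_count
  )
  passes$least_concern <- passes$eoo_pass & passes$aoo_pass &
    passes$records_pass & passes$tdwg_pass & !nzchar(warning_txt)
  passes$warning <- warning_txt
  class(passes) <- c("gauge_result", class(passes))
  passes
}

#' Classify a batch of species against Least Concern thresholds
#'
#' Produces the batch results table: one row per screened species, in input
#' order, with the raw statistics, the Least Concern flag under the supplied
#' thresholds and any warning. Re-running with different thresholds changes
#' only the `least_concern` flags, never the metrics.
#'
#' @param rows A data frame with columns `full_name`, `powo_id`, `eoo_km2`,
#'   `aoo_km2`, `record_count`, `tdwg_count` and optionally `warning`.
#' @param thresholds An [lc_thresholds()].
#' @return A tibble with columns `full_name`, `powo_id`, `eoo_km2`,
#'   `aoo_km2`, `record_count`, `tdwg_count`, `least_concern`, `warning`.
#' @export
classify_batch <- function(rows, thresholds = lc_thresholds()) {
  rows <- tibble::as_tibble(rows)
  if (nrow(rows) == 0L) {
    return(tibble::tibble(
      full_name = character(), powo_id = character(), eoo_km2 = numeric(),
      aoo_km2 = numeric(), record_count = integer(), tdwg_count = integer(),
      least_concern = logical(), warning = character()
    ))
  }
  if (!"warning" %in% names(rows)) rows$warning <- ""
  rows$warning[is.na(rows$warning)] <- ""
  rows$least_concern <- rows$eoo_km2 >= thresholds$eoo_km2 &
    rows$aoo_km2 >= thresholds$aoo_km2 &
    rows$record_count >= thresholds$record_count &
    rows$tdwg_count >= thresholds$tdwg_count &
    !nzchar(rows$warning)
  rows[, c("full_name", "powo_id", "eoo_km2", "aoo_km2", "record_count",
           "tdwg_count", "least_concern", "warning")]
}
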