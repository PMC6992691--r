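# Threshold calibration by confusion-matrix sensitivity sweeps.
#
# Published Red List categories are reduced to a binary truth - LC is the
# positive class; threatened categories and NT are negative (the tool's task
# is isolating LC from everything of elevated concern); DD and NE are
# excluded. Each parameter is swept independently over a threshold grid:
# prediction at a grid value is positive iff that single parameter's metric
# meets or exceeds the threshold.

sweep_parameters <- c(
  eoo = "eoo_km2", aoo = "aoo_km2",
  records = "record_count", tdwg = "tdwg_count"
)

category_truth <- function(category) {
  category <- toupper(category)
  ifelse(category == "LC", TRUE,
         ifelse(category %in% c("NT", "VU", "EN", "CR", "EW", "EX"),
                FALSE, NA))
}

#' Prepare validation records from published assessments
#'
#' @param records A data frame with columns `name`, `category` (Red List
#'   code) and the four metric columns `eoo_km2`, `aoo_km2`, `record_count`,
#'   `tdwg_count`.
#' @return The table with a logical `truth` column (LC positive), DD/NE rows
#'   excluded.
#' @export
validation_records <- function(records) {
  records <- tibble::as_tibble(records)
  required <- c("name", "category", unname(sweep_parameters))
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    abort_schema(paste0("validation table lacks columns: ",
                        paste(missing, collapse = ", ")),
                 missing = missing)
  }
  records$truth <- category_truth(records$category)
  records[!is.na(records$truth), , drop = FALSE]
}

#' Sweep one parameter's threshold and score against published categories
#'
#' For each grid value, every species is predicted Least Concern iff the
#' swept parameter's metric meets or exceeds that threshold; predictions are
#' tallied against the published categories in a confusion matrix.
#'
#' @param records Output of [validation_records()] (or a raw table, which is
#'   passed through it).
#' @param parameter One of `"eoo"`, `"aoo"`, `"records"`, `"tdwg"`.
#' @param grid Ascending vector of threshold values.
#' @return A tibble with one row per grid value: `parameter`, `threshold`,
#'   `tp`, `fp`, `tn`, `fn`, `accuracy`, `tpr`, `fpr`. Rates are `NaN` when a
#'   truth class is empty.
#' @export
sweep_threshold <- function(records, parameter, grid) {
  if (!parameter %in% names(sweep_parameters)) {
    abort_config(paste0(
      "unknown parameter '", parameter, "'; use one of: ",
      paste(names(sweep_parameters), collapse = ", ")
    ))
  }
  if (length(grid) == 0L || is.unsorted(grid, strictly = FALSE)) {
    abort_config("`grid` must be a non-empty ascending vector of thresholds.")
  }
  if (!"truth" %in% names(records)) records <- validation_records(records)
  if (nrow(records) == 0L) {
    abort_config("no validation records after excluding DD/NE categories.")
  }
  metric <- records[[sweep_parameters[[parameter]]]]
  truth <- records$truth
  purrr::map_dfr(grid, function(th) {
    pred <- metric >= th
    tp <- sum(pred & truth)
    fp <- sum(pred & !truth)
    tn <- sum(!pred & !truth)
    fn <- sum(!pred & truth)
    tibble::tibble(
      parameter = parameter, threshold = th,
      tp = tp, fp = fp, tn = tn, fn = fn,
      accuracy = (tp + tn) / (tp + fp + tn + fn),
      tpr = tp / (tp + fn),
      fpr = fp / (fp + tn)
    )
  })
}

#' Sweep all four parameters
#'
#' Runs [sweep_threshold()] for each parameter over its own grid and marks
#' the chosen (default) threshold for plotting the calibration curves.
#'
#' @param records Validation table (see [validation_records()]).
#' @param grids Named list of ascending grids for `eoo`, `aoo`, `records`,
#'   `tdwg`; defaults span the default thresholds.
#' @param chosen An [lc_thresholds()] marking the selected values.
#' @return A tidy tibble of the four curves with a `chosen_threshold`
#'   column.
#' @export
sweep_all <- function(records,
                      grids = list(
                        eoo = seq(1000, 100000, by = 1000),
                        aoo = seq(100, 10000, by = 100),
                        records = seq(5, 250, by = 5),
                        tdwg = 1:20
                      ),
                      chosen = lc_thresholds()) {
  records <- validation_records(records)
  chosen_map <- c(eoo = chosen$eoo_km2, aoo = chosen$aoo_km2,
                  records = chosen$record_count, tdwg = chosen$tdwg_count)
  purrr::map_dfr(names(sweep_parameters), function(p) {
    curve <- sweep_threshold(records, p, grids[[p]])
    curve$chosen_threshold <- chosen_map[[p]]
    curve
  })
}
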