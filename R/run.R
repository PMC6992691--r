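# End-to-end workflows mirroring the single-species and batch screening
# modes, plus the user-occurrence variant and the sensitivity run. These are
# what the command-line interface wraps; they are ordinary functions so they
# compose in scripts and tests.

#' Assemble a run configuration
#'
#' @param mode One of `"single"`, `"batch"`, `"batch-user-points"`,
#'   `"sensitivity"`.
#' @param occ_limit Occurrence-record limit (1000-10000, default 3000).
#' @param thresholds An [lc_thresholds()].
#' @param batch_limit Maximum species per batch (default 100).
#' @param cell_km AOO grid cell side in km (default 10).
#' @param out_dir Output directory for bundles and tables.
#' @param accept_lc Write SIS bundles without interactive review. The
#'   screening suggestion is precisely that — a suggestion; by default
#'   nothing is written until the operator accepts it.
#' @param seed Integer seed for any stochastic step.
#' @return A `run_config` list with bounds enforced.
#' @export
run_config <- function(mode = c("single", "batch", "batch-user-points",
                                "sensitivity"),
                       occ_limit = 3000L, thresholds = lc_thresholds(),
                       batch_limit = 100L, cell_km = 10, out_dir = ".",
                       accept_lc = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  if (!is_scalar_number(occ_limit) || occ_limit < 1000 || occ_limit > 10000) {
    abort_config("`occ_limit` must be between 1,000 and 10,000 (default 3,000).")
  }
  stopifnot(inherits(thresholds, "lc_thresholds"))
  structure(
    list(mode = mode, occ_limit = as.integer(occ_limit),
         thresholds = thresholds, batch_limit = as.integer(batch_limit),
         cell_km = cell_km, out_dir = out_dir,
         accept_lc = isTRUE(accept_lc), seed = as.integer(seed)),
    class = "run_config"
  )
}

screen_one <- function(input_name, match, range, occ, store, config) {
  filtered <- filter_to_native(clean_records(occ), range, store)
  metrics <- compute_metrics(filtered, cell_km = config$cell_km)
  row <- classify_batch(
    tibble::tibble(
      full_name = match$canonical_name, powo_id = range$powo_id,
      eoo_km2 = metrics$eoo_km2, aoo_km2 = metrics$aoo_km2,
      record_count = metrics$record_count, tdwg_count = metrics$tdwg_count,
      warning = metrics$warning
    ),
    config$thresholds
  )
  list(row = row, filtered = filtered, metrics = metrics,
       gauges = evaluate(metrics, config$thresholds))
}

#' Run the single-species workflow
#'
#' Resolves the name, looks up the native range, fetches and cleans
#' occurrences, filters to the native range, computes the four range
#' statistics and evaluates the Least Concern gauges. Writes a SIS bundle
#' only when the species passes and `config$accept_lc` is set.
#'
#' @param name Binomial to screen.
#' @param backbone,provider,occ_backend,store Injected backends.
#' @param config A [run_config()].
#' @return A list: `match`, `range`, `results` (one-row table), `gauges`,
#'   and `bundle_paths` (`NULL` unless a bundle was written).
#' @export
run_single <- function(name, backbone, provider, occ_backend, store,
                       config = run_config("single")) {
  query <- taxon_query(name)
  if (!query$is_binomial) {
    abort_config(paste0("'", name, "' is not a binomial (Genus species)."))
  }
  matches <- match_name(query, backbone)
  if (nrow(matches) == 0L) {
    abort(paste0("no name match found for '", query$normalized_name, "'."),
          class = "lcscreen_no_match")
  }
  best <- matches[1, , drop = FALSE]
  range <- lookup_native_range(best, provider)
  if (is.null(range)) {
    abort(paste0("no checklist record for '", best$canonical_name, "'."),
          class = "lcscreen_no_match")
  }
  occ <- fetch_occurrences(best$usage_key, occ_backend,
                           limit = config$occ_limit)
  scr <- screen_one(query$normalized_name, best, range, occ, store, config)
  bundle_paths <- NULL
  if (scr$row$least_concern && config$accept_lc) {
    taxa <- dplyr::mutate(scr$row,
      authorship = best$authorship, family = best$family,
      range = list(range),
      points = list(scr$filtered$retained$records[, c("longitude", "latitude")])
    )
    bundle <- build_bundle(taxa)
    bundle_paths <- write_bundle(bundle, config$out_dir)
  }
  list(match = best, range = range, results = scr$row, gauges = scr$gauges,
       bundle_paths = bundle_paths)
}

#' Run the batch workflow
#'
#' Pre-screens the names against the checklist (synonyms and unmatched names
#' are excluded and reported), runs the single-species analysis for each
#' accepted name, and returns the results table covering every input name,
#' with warnings where metrics could not be computed. When
#' `config$accept_lc` is set, a SIS bundle for the Least Concern subset is
#' written to `config$out_dir` together with the results CSV.
#'
#' @param names Character vector of binomials (at most the batch limit), or
#'   a path to a one-column headered CSV of names.
#' @param backbone,provider,occ_backend,store Injected backends.
#' @param config A [run_config()].
#' @param user_occurrences Optional named list of [occurrence_set()] (as
#'   from [load_user_occurrences()]); when given, the occurrence backend is
#'   bypassed and sets are matched to input names.
#' @return A list: `screen` (the batch screen report), `results` (tibble,
#'   one row per input name), `bundle_paths` (`NULL` unless written).
#' @export
run_batch <- function(names, backbone, provider, occ_backend, store,
                      config = run_config("batch"),
                      user_occurrences = NULL) {
  if (length(names) == 1L && file.exists(names)) {
    tbl <- readr::read_csv(names, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    names <- tbl[[1]]
  }
  screen <- screen_batch(names, backbone, provider,
                         batch_limit = config$batch_limit)
  acc <- screen$accepted
  rows <- list()
  bundle_taxa <- list()
  for (i in seq_len(nrow(acc))) {
    best <- acc[i, , drop = FALSE]
    range <- acc$range[[i]]
    occ <- if (!is.null(user_occurrences)) {
      user_occurrences[[best$input_name]] %||%
        occurrence_set(tibble::tibble(longitude = numeric(),
                                      latitude = numeric()),
                       taxon_ref = best$input_name)
    } else {
      fetch_occurrences(best$usage_key, occ_backend,
                        limit = config$occ_limit)
    }
    scr <- screen_one(best$input_name, best, range, occ, store, config)
    rows <- c(rows, list(scr$row))
    if (scr$row$least_concern) {
      bundle_taxa <- c(bundle_taxa, list(dplyr::mutate(
        scr$row, authorship = best$authorship, family = best$family,
        range = list(range),
        points = list(scr$filtered$retained$records[, c("longitude",
                                                        "latitude")])
      )))
    }
  }
  excluded <- tibble::tibble(
    full_name = c(screen$excluded_synonyms$input_name, screen$unmatched),
    powo_id = NA_character_, eoo_km2 = NA_real_, aoo_km2 = NA_real_,
    record_count = NA_integer_, tdwg_count = NA_integer_,
    least_concern = FALSE,
    warning = c(
      paste0("synonym of ", screen$excluded_synonyms$accepted_name,
             "; excluded from analysis"),
      rep("name not matched to the checklist", length(screen$unmatched))
    )
  )
  results <- dplyr::bind_rows(c(rows, list(excluded)))
  bundle_paths <- NULL
  if (config$accept_lc && length(bundle_taxa)) {
    bundle <- build_bundle(dplyr::bind_rows(bundle_taxa))
    bundle_paths <- write_bundle(bundle, config$out_dir)
    readr::write_csv(results, file.path(config$out_dir, "results.csv"),
                     progress = FALSE)
  }
  list(screen = screen, results = results, bundle_paths = bundle_paths)
}

#' Run a threshold sensitivity analysis
#'
#' Sweeps the four parameters over threshold grids against a validation
#' table of published categories and writes the tidy curves CSV.
#'
#' @param records Validation table or path to its CSV (columns `name`,
#'   `category`, `eoo_km2`, `aoo_km2`, `record_count`, `tdwg_count`).
#' @param config A [run_config()].
#' @param grids,chosen Passed to [sweep_all()].
#' @param out_file Optional path for the curves CSV.
#' @return The tidy curves tibble.
#' @export
run_sensitivity <- function(records, config = run_config("sensitivity"),
                            grids = NULL, chosen = config$thresholds,
                            out_file = NULL) {
  if (is.character(records) && length(records) == 1L) {
    records <- readr::read_csv(
      records, col_types = readr::cols(
        name = "c", category = "c", .default = "d"), progress = FALSE)
  }
  curves <- if (is.null(grids)) {
    sweep_all(records, chosen = chosen)
  } else {
    sweep_all(records, grids = grids, chosen = chosen)
  }
  if (!is.null(out_file)) readr::write_csv(curves, out_file, progress = FALSE)
  curves
}
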