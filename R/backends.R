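# Injected backend interfaces. A backend is a plain list of functions so live
# HTTP clients, fixtures and deliberately-failing test doubles are
# interchangeable. Fixtures are canned JSON documents mimicking the response
# shapes of the live services; everything in the package runs offline.

#' Build an offline name backbone from a candidate table
#'
#' The backbone holds accepted names and synonyms and answers fuzzy queries:
#' an exact (case-insensitive) hit scores confidence 99, near misses are
#' scored down by Levenshtein edit distance (`99 - 15 * distance`, at most 2
#' edits on the binomial), and genus-only queries fall back to a HIGHERRANK
#' match on the genus at confidence 80.
#'
#' @param entries A data frame with columns `canonical_name`, `authorship`,
#'   `family`, `usage_key`, `is_synonym` and (for synonyms) `accepted_name`.
#' @return A name backend usable with [match_name()].
#' @export
name_backbone <- function(entries) {
  entries <- tibble::as_tibble(entries)
  required <- c("canonical_name", "authorship", "family", "usage_key",
                "is_synonym")
  missing <- setdiff(required, names(entries))
  if (length(missing)) {
    abort_schema(paste0("backbone table lacks columns: ",
                        paste(missing, collapse = ", ")),
                 missing = missing)
  }
  if (!"accepted_name" %in% names(entries)) {
    entries$accepted_name <- entries$canonical_name
  }
  entries$accepted_name <- ifelse(
    entries$is_synonym, entries$accepted_name, entries$canonical_name
  )
  entries$usage_key <- as.character(entries$usage_key)

  list(
    entries = entries,
    match = function(name) {
      dist <- as.integer(utils::adist(
        tolower(name), tolower(entries$canonical_name)
      ))
      hit <- dist <= 2L
      out <- entries[hit, , drop = FALSE]
      if (nrow(out) > 0L) {
        d <- dist[hit]
        out$match_type <- ifelse(d == 0L, "EXACT", "FUZZY")
        out$confidence <- pmax(0, 99 - 15 * d)
        return(out[, c("canonical_name", "authorship", "family", "usage_key",
                       "confidence", "match_type", "is_synonym",
                       "accepted_name")])
      }
      # higher-rank fallback: genus matches even though the epithet does not
      genus <- sub(" .*$", "", tolower(name))
      bg <- sub(" .*$", "", tolower(entries$canonical_name))
      out <- entries[bg == genus, , drop = FALSE]
      if (nrow(out) == 0L) return(NULL)
      out <- out[1, , drop = FALSE]
      out$match_type <- "HIGHERRANK"
      out$confidence <- 80
      out[, c("canonical_name", "authorship", "family", "usage_key",
              "confidence", "match_type", "is_synonym", "accepted_name")]
    }
  )
}

#' Build an offline native-range provider
#'
#' @param ranges A data frame with columns `usage_key`, `powo_id`,
#'   `native_codes` and `introduced_codes` (list-columns of character codes,
#'   or single space-separated strings).
#' @return A range backend usable with [lookup_native_range()].
#' @export
range_provider <- function(ranges) {
  ranges <- tibble::as_tibble(ranges)
  split_codes <- function(x) {
    if (is.list(x)) lapply(x, as.character)
    else strsplit(ifelse(is.na(x) | !nzchar(x), "", x), "[ ,]+")
  }
  ranges$native_codes <- split_codes(ranges$native_codes)
  ranges$introduced_codes <- split_codes(ranges$introduced_codes)
  ranges$usage_key <- as.character(ranges$usage_key)
  list(
    ranges = ranges,
    lookup = function(usage_key, canonical_name = NULL) {
      i <- match(as.character(usage_key), ranges$usage_key)
      if (is.na(i)) return(NULL)
      list(
        powo_id = ranges$powo_id[[i]],
        native_codes = ranges$native_codes[[i]],
        introduced_codes = ranges$introduced_codes[[i]]
      )
    }
  )
}

#' Build an offline occurrence backend
#'
#' Emulates an occurrence web service: records are keyed by backbone usage
#' key and served in stable order with the total count reported, so callers
#' can detect truncation.
#'
#' @param occurrences A data frame with columns `usage_key`,
#'   `decimalLongitude`, `decimalLatitude`, `source_id` and
#'   `hasGeospatialIssue`. Missing coordinates mark non-georeferenced records.
#' @return An occurrence backend usable with [fetch_occurrences()].
#' @export
occurrence_backend <- function(occurrences) {
  occurrences <- tibble::as_tibble(occurrences)
  occurrences$usage_key <- as.character(occurrences$usage_key)
  if (!"hasGeospatialIssue" %in% names(occurrences)) {
    occurrences$hasGeospatialIssue <- FALSE
  }
  if (!"source_id" %in% names(occurrences)) {
    occurrences$source_id <- as.character(seq_len(nrow(occurrences)))
  }
  list(
    occurrences = occurrences,
    search = function(usage_key, limit) {
      rec <- occurrences[occurrences$usage_key == as.character(usage_key), ,
                         drop = FALSE]
      usable <- !is.na(rec$decimalLongitude) & !is.na(rec$decimalLatitude) &
        !rec$hasGeospatialIssue
      rec <- rec[usable, , drop = FALSE]
      total <- nrow(rec)
      list(
        records = utils::head(rec, limit),
        total = total
      )
    }
  )
}

#' Read fixture backends from canned JSON documents
#'
#' Each fixture file is a JSON document holding the same table the in-memory
#' constructor takes; see [write_fixture_backends()] for the writer.
#'
#' @param path Path to a fixture JSON file.
#' @return The corresponding backend.
#' @name fixture-backends
NULL

#' @rdname fixture-backends
#' @export
read_name_backbone <- function(path) {
  name_backbone(jsonlite::fromJSON(path))
}

#' @rdname fixture-backends
#' @export
read_range_provider <- function(path) {
  tbl <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  range_provider(tbl)
}

#' @rdname fixture-backends
#' @export
read_occurrence_backend <- function(path) {
  occurrence_backend(jsonlite::fromJSON(path))
}

#' Bundled demonstration fixtures
#'
#' Returns the directory of the small fixture set shipped with the package
#' (name backbone, range provider, occurrence backend and a toy region
#' store), used by the examples and the command-line interface's fixture
#' mode.
#'
#' @return A directory path.
#' @export
bundled_fixture_dir <- function() {
  system.file("extdata", "fixtures", package = "lcscreen", mustWork = TRUE)
}
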