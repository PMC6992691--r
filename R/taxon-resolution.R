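#' Parse a user-entered plant name into a taxon query
#'
#' Normalises whitespace, capitalises the genus and lower-cases the epithet.
#' Infraspecific rank markers (var., subsp., ssp., f., forma) and anything
#' after them are stripped and flagged: only binomials proceed through the
#' screening pipeline.
#'
#' @param raw_name Species name as entered, e.g. `"Aloe zebrina"`.
#' @return A `taxon_query` object with fields `raw_name`, `normalized_name`,
#'   `is_binomial` and `had_infraspecific`.
#' @examples
#' taxon_query("  aloe   ZEBRINA ")
#' taxon_query("Poa annua var. aquatica")
#' @export
taxon_query <- function(raw_name) {
  stopifnot(is.character(raw_name), length(raw_name) == 1L)
  norm <- trimws(gsub("\\s+", " ", raw_name))
  had_infra <- FALSE
  rank_re <- "\\s+(var\\.|subsp\\.|ssp\\.|f\\.|forma)(\\s.*)?$"
  if (grepl(rank_re, norm)) {
    norm <- sub(rank_re, "", norm)
    had_infra <- TRUE
  }
  parts <- strsplit(norm, " ", fixed = TRUE)[[1]]
  is_binomial <- length(parts) >= 2L && all(nzchar(parts[1:2]))
  if (length(parts) >= 1L && nzchar(parts[[1]])) {
    parts[[1]] <- paste0(
      toupper(substr(parts[[1]], 1, 1)),
      tolower(substr(parts[[1]], 2, nchar(parts[[1]])))
    )
  }
  if (length(parts) >= 2L) parts[-1] <- tolower(parts[-1])
  norm <- paste(parts[seq_len(min(length(parts), 2L))], collapse = " ")
  structure(
    list(
      raw_name = raw_name,
      normalized_name = norm,
      is_binomial = is_binomial,
      had_infraspecific = had_infra
    ),
    class = "taxon_query"
  )
}

#' @export
print.taxon_query <- function(x, ...) {
  cat("<taxon_query> ", x$normalized_name,
      if (!x$is_binomial) " [not a binomial]" else "",
      if (x$had_infraspecific) " [infraspecific rank stripped]" else "",
      "\n", sep = "")
  invisible(x)
}

match_type_rank <- c(EXACT = 1L, FUZZY = 2L, HIGHERRANK = 3L, NONE = 4L)

empty_match_results <- function() {
  tibble::tibble(
    canonical_name = character(),
    authorship = character(),
    family = character(),
    usage_key = character(),
    confidence = numeric(),
    match_type = character(),
    is_synonym = logical(),
    accepted_name = character()
  )
}

#' Match a name against a name backbone
#'
#' Runs a fuzzy search of the injected name backbone (an offline fixture of
#' the GBIF species backbone, or any backend implementing the same contract)
#' and returns candidate matches sorted best-first: by confidence descending,
#' ties broken by match type (EXACT before FUZZY before HIGHERRANK), then
#' alphabetically by canonical name.
#'
#' @param query A [taxon_query()].
#' @param backbone A name backend, e.g. [name_backbone()].
#' @return A tibble of match candidates with columns `canonical_name`,
#'   `authorship`, `family`, `usage_key`, `confidence` (0-100), `match_type`
#'   (EXACT, FUZZY or HIGHERRANK), `is_synonym` and `accepted_name`. Zero rows
#'   when the backbone has no candidate.
#' @export
match_name <- function(query, backbone) {
  stopifnot(inherits(query, "taxon_query"))
  if (!nzchar(query$normalized_name)) {
    abort_config("`query` has an empty normalized name; nothing to match.")
  }
  res <- backbone$match(query$normalized_name)
  if (is.null(res) || nrow(res) == 0L) return(empty_match_results())
  stopifnot(all(res$confidence >= 0 & res$confidence <= 100))
  ord <- order(
    -res$confidence,
    match_type_rank[res$match_type],
    res$canonical_name
  )
  res[ord, , drop = FALSE]
}

#' Construct a native/introduced range-code set
#'
#' @param powo_id Opaque checklist identifier for the accepted taxon.
#' @param native_codes,introduced_codes Character vectors of WGSRPD Level-3
#'   codes (uppercase, three letters). The two sets must be disjoint.
#' @return A `native_range` object.
#' @export
native_range <- function(powo_id, native_codes = character(),
                         introduced_codes = character()) {
  native_codes <- unique(toupper(as.character(native_codes)))
  introduced_codes <- unique(toupper(as.character(introduced_codes)))
  bad <- c(native_codes, introduced_codes)
  bad <- bad[!grepl("^[A-Z]{3}$", bad)]
  if (length(bad)) {
    abort_config(paste0(
      "WGSRPD Level-3 codes must be three uppercase letters; invalid: ",
      paste(bad, collapse = ", ")
    ))
  }
  overlap <- intersect(native_codes, introduced_codes)
  if (length(overlap)) {
    abort_config(paste0(
      "native and introduced code sets overlap: ",
      paste(overlap, collapse = ", ")
    ))
  }
  structure(
    list(
      powo_id = powo_id,
      native_codes = native_codes,
      introduced_codes = introduced_codes
    ),
    class = "native_range"
  )
}

#' @export
print.native_range <- function(x, ...) {
  cat("<native_range> ", x$powo_id, "\n",
      "  native:     ", paste(x$native_codes, collapse = " "), "\n",
      "  introduced: ", paste(x$introduced_codes, collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Look up the native range of a matched taxon
#'
#' Queries the injected range provider (an offline fixture of the POWO
#' checklist, or a live client with the same contract) for the WGSRPD Level-3
#' codes where the taxon is native and where it is introduced. A taxon absent
#' from the provider is a value (`NULL`), not an error.
#'
#' @param match A single-row match result (one row of [match_name()] output).
#' @param provider A range backend, e.g. [range_provider()].
#' @return A [native_range()], or `NULL` when the provider has no record.
#' @export
lookup_native_range <- function(match, provider) {
  stopifnot(is.data.frame(match), nrow(match) == 1L)
  if (identical(match$match_type, "NONE")) {
    abort_config("cannot look up a range for an unmatched name.")
  }
  rec <- provider$lookup(match$usage_key, match$canonical_name)
  if (is.null(rec)) return(NULL)
  native_range(rec$powo_id, rec$native_codes, rec$introduced_codes)
}

#' Pre-screen a batch of names against the checklist
#'
#' Matches each name, then partitions the batch: names whose best match is a
#' synonym are excluded (with their accepted name surfaced so the user can
#' resubmit), names with no checklist record are reported unmatched, and only
#' accepted names proceed to the occurrence analysis.
#'
#' @param names Character vector of binomials, or a list of [taxon_query()]
#'   objects. At most `batch_limit` names.
#' @param backbone,provider Injected backends (see [name_backbone()],
#'   [range_provider()]).
#' @param batch_limit Maximum batch size, default 100.
#' @return A `batch_screen_report`: list with `accepted` (tibble of input
#'   name, match columns, and a `range` list-column of [native_range()]),
#'   `excluded_synonyms` (tibble of input name + accepted name) and
#'   `unmatched` (character vector).
#' @export
screen_batch <- function(names, backbone, provider, batch_limit = 100L) {
  if (is.character(names)) names <- lapply(names, taxon_query)
  if (length(names) == 0L) {
    abort_config("batch is empty; supply at least one name.")
  }
  if (length(names) > batch_limit) {
    abort_config(sprintf(
      "batch of %d names exceeds the limit of %d species at a time.",
      length(names), batch_limit
    ))
  }
  accepted <- list()
  synonyms <- list()
  unmatched <- character()
  for (q in names) {
    input <- q$normalized_name
    res <- if (q$is_binomial) match_name(q, backbone) else empty_match_results()
    if (nrow(res) == 0L) {
      unmatched <- c(unmatched, input)
      next
    }
    best <- res[1, , drop = FALSE]
    if (isTRUE(best$is_synonym)) {
      synonyms <- c(synonyms, list(tibble::tibble(
        input_name = input, accepted_name = best$accepted_name
      )))
      next
    }
    range <- lookup_native_range(best, provider)
    if (is.null(range)) {
      unmatched <- c(unmatched, input)
      next
    }
    accepted <- c(accepted, list(
      dplyr::mutate(best, input_name = input, range = list(range),
                    .before = 1)
    ))
  }
  structure(
    list(
      accepted = if (length(accepted)) dplyr::bind_rows(accepted) else
        dplyr::mutate(empty_match_results(), input_name = character(),
                      range = list(), .before = 1),
      excluded_synonyms = if (length(synonyms)) dplyr::bind_rows(synonyms) else
        tibble::tibble(input_name = character(), accepted_name = character()),
      unmatched = unmatched
    ),
    class = "batch_screen_report"
  )
}

#' @export
print.batch_screen_report <- function(x, ...) {
  cat("<batch_screen_report>\n",
      "  accepted:          ", nrow(x$accepted), "\n",
      "  excluded synonyms: ", nrow(x$excluded_synonyms), "\n",
      "  unmatched:         ", length(x$unmatched), "\n", sep = "")
  invisible(x)
}
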