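# SIS Connect bundle assembly: the seven cross-linked CSV tables (allfields,
# assessments, countries, credits, habitats, plantspecific, taxonomy) plus
# the point-distribution table, all keyed by internal_taxon_id. Column
# schemas are not fixed in code: they ship as a versioned YAML config so
# schema drift against the upload service is a config change.

sis_table_names <- c("allfields", "assessments", "countries", "credits",
                     "habitats", "plantspecific", "taxonomy")

#' Read the SIS bundle schema configuration
#'
#' @param path YAML schema file; the bundled versioned default when omitted.
#' @return A list with `version`, per-table column definitions and default
#'   field values.
#' @export
sis_schema <- function(path = system.file("extdata", "sis_schema.yaml",
                                          package = "lcscreen",
                                          mustWork = TRUE)) {
  yaml::read_yaml(path)
}

#' Default assessment field values
#'
#' Field values shared by every generated Least Concern assessment. The
#' category is fixed to "LC" for this pipeline; the rationale template takes
#' the binomial via `{name}`.
#'
#' @param category_code Red List category code; fixed to `"LC"`.
#' @param rationale_template Rationale text with a `{name}` placeholder.
#' @param population_trend,ecological_system,habitat_code,habitat_name
#'   Documentation defaults; all overridable.
#' @param bibliography Character vector of citation strings for the data
#'   sources used.
#' @param assessor Name recorded in the credits table.
#' @return An `assessment_defaults` list.
#' @export
assessment_defaults <- function(
    category_code = "LC",
    rationale_template = paste0(
      "{name} is a widespread species with a large extent of occurrence ",
      "and area of occupancy that exceed the thresholds for threatened ",
      "categories, and no current widespread threats have been identified. ",
      "It is therefore assessed as Least Concern."),
    population_trend = "Unknown",
    ecological_system = "Terrestrial",
    habitat_code = "18",
    habitat_name = "Unknown",
    bibliography = c(
      "GBIF: The Global Biodiversity Information Facility. Occurrence download.",
      "POWO. Plants of the World Online. Royal Botanic Gardens, Kew."),
    assessor = "Unknown") {
  if (!identical(category_code, "LC")) {
    abort_config("this pipeline documents Least Concern assessments only; category_code must be \"LC\".")
  }
  structure(
    list(category_code = category_code,
         rationale_template = rationale_template,
         population_trend = population_trend,
         ecological_system = ecological_system,
         habitat_code = habitat_code,
         habitat_name = habitat_name,
         bibliography = bibliography,
         assessor = assessor),
    class = "assessment_defaults"
  )
}

#' WGSRPD Level-3 code to country lookup
#'
#' @param path Lookup CSV (`l3_code`, `country`, `iso2`); the bundled subset
#'   when omitted. Codes absent from the lookup map to themselves.
#' @return A tibble.
#' @export
l3_country_lookup <- function(path = system.file(
    "extdata", "tdwg_l3_countries.csv", package = "lcscreen",
    mustWork = TRUE)) {
  readr::read_csv(path, col_types = "ccc", progress = FALSE)
}

taxon_field <- function(taxa, i, field, default = "") {
  v <- taxa[[field]]
  if (is.null(v)) return(default)
  out <- v[[i]]
  if (is.null(out) || is.na(out)) default else out
}

#' Build a SIS Connect assessment bundle
#'
#' Assembles the seven cross-linked documentation tables plus the point
#' table for a set of species accepted as Least Concern. Internal taxon ids
#' are assigned sequentially from 1 in input order. Countries rows are
#' derived from the native Level-3 codes through the bundled code-to-country
#' lookup; one-to-many tables (countries, habitats, credits) may repeat the
#' key.
#'
#' @param taxa A data frame with one row per taxon: columns `full_name`,
#'   `authorship`, `family`, `powo_id`, `least_concern`, a `range`
#'   list-column of [native_range()], and a `points` list-column of
#'   point tables (`longitude`, `latitude`). Optional: `eoo_km2`, `aoo_km2`,
#'   `record_count`, `tdwg_count`.
#' @param defaults An [assessment_defaults()].
#' @param schema A [sis_schema()].
#' @param lookup A [l3_country_lookup()] table.
#' @return An `sis_bundle`: list of the seven tables plus `points`.
#' @export
build_bundle <- function(taxa, defaults = assessment_defaults(),
                         schema = sis_schema(),
                         lookup = l3_country_lookup()) {
  taxa <- tibble::as_tibble(taxa)
  if (nrow(taxa) > 0L && !all(taxa$least_concern)) {
    bad <- taxa$full_name[!taxa$least_concern]
    abort_config(paste0(
      "bundle accepts Least Concern species only; not LC: ",
      paste(bad, collapse = ", ")
    ))
  }
  n <- nrow(taxa)
  ids <- as.numeric(seq_len(n))
  rows <- lapply(ids, function(i) {
    name <- taxa$full_name[[i]]
    genus <- sub(" .*$", "", name)
    species <- sub("^\\S+\\s*", "", name)
    range <- taxa$range[[i]]
    codes <- if (!is.null(range)) range$native_codes else character()
    countries <- dplyr::left_join(
      tibble::tibble(l3_code = codes), lookup, by = "l3_code"
    )
    countries$country[is.na(countries$country)] <-
      countries$l3_code[is.na(countries$country)]
    pts <- taxa$points[[i]]
    list(
      taxonomy = tibble::tibble(
        internal_taxon_id = i, family = taxon_field(taxa, i, "family"),
        genus = genus, species = species,
        taxonomicAuthority = taxon_field(taxa, i, "authorship")
      ),
      assessments = tibble::tibble(
        internal_taxon_id = i,
        RedListCategory = defaults$category_code,
        RedListRationale = gsub("{name}", name,
                                defaults$rationale_template, fixed = TRUE),
        PopulationTrend = defaults$population_trend,
        EcologicalSystem = defaults$ecological_system,
        Bibliography = paste(defaults$bibliography, collapse = " | ")
      ),
      allfields = tibble::tibble(
        internal_taxon_id = i,
        EOO_km2 = as.numeric(taxon_field(taxa, i, "eoo_km2", NA_real_)),
        AOO_km2 = as.numeric(taxon_field(taxa, i, "aoo_km2", NA_real_)),
        RecordCount = as.numeric(taxon_field(taxa, i, "record_count", NA_real_)),
        TDWGCount = as.numeric(taxon_field(taxa, i, "tdwg_count", NA_real_))
      ),
      countries = tibble::tibble(
        internal_taxon_id = rep(i, nrow(countries)),
        country = countries$country,
        iso2 = countries$iso2 %||% rep(NA_character_, nrow(countries)),
        l3_code = countries$l3_code,
        origin = rep("Native", nrow(countries)),
        presence = rep("Extant", nrow(countries))
      ),
      credits = tibble::tibble(
        internal_taxon_id = i, credit_type = "Assessor",
        name = defaults$assessor
      ),
      habitats = tibble::tibble(
        internal_taxon_id = i,
        GeneralHabitats = defaults$habitat_code,
        GeneralHabitatsName = defaults$habitat_name
      ),
      plantspecific = tibble::tibble(
        internal_taxon_id = i, GrowthForms = "Unknown"
      ),
      points = tibble::tibble(
        internal_taxon_id = rep(i, NROW(pts)),
        binomial = rep(name, NROW(pts)),
        longitude = if (NROW(pts)) pts$longitude else numeric(),
        latitude = if (NROW(pts)) pts$latitude else numeric(),
        presence = rep("Extant", NROW(pts)),
        origin = rep("Native", NROW(pts)),
        seasonal = rep("Resident", NROW(pts))
      )
    )
  })
  pick <- function(tbl) {
    out <- dplyr::bind_rows(lapply(rows, `[[`, tbl))
    if (nrow(out) == 0L) out <- empty_bundle_tables[[tbl]]
    out
  }
  bundle <- lapply(c(sis_table_names, "points"), pick)
  names(bundle) <- c(sis_table_names, "points")
  structure(bundle, class = "sis_bundle", schema_version = schema$version)
}

# Zero-row prototypes so an empty bundle still writes header-only CSVs with
# the full column set.
empty_bundle_tables <- list(
  taxonomy = tibble::tibble(
    internal_taxon_id = numeric(), family = character(), genus = character(),
    species = character(), taxonomicAuthority = character()
  ),
  assessments = tibble::tibble(
    internal_taxon_id = numeric(), RedListCategory = character(),
    RedListRationale = character(), PopulationTrend = character(),
    EcologicalSystem = character(), Bibliography = character()
  ),
  allfields = tibble::tibble(
    internal_taxon_id = numeric(), EOO_km2 = numeric(), AOO_km2 = numeric(),
    RecordCount = numeric(), TDWGCount = numeric()
  ),
  countries = tibble::tibble(
    internal_taxon_id = numeric(), country = character(), iso2 = character(),
    l3_code = character(), origin = character(), presence = character()
  ),
  credits = tibble::tibble(
    internal_taxon_id = numeric(), credit_type = character(),
    name = character()
  ),
  habitats = tibble::tibble(
    internal_taxon_id = numeric(), GeneralHabitats = character(),
    GeneralHabitatsName = character()
  ),
  plantspecific = tibble::tibble(
    internal_taxon_id = numeric(), GrowthForms = character()
  ),
  points = tibble::tibble(
    internal_taxon_id = numeric(), binomial = character(),
    longitude = numeric(), latitude = numeric(), presence = character(),
    origin = character(), seasonal = character()
  )
)

#' Build an empty, valid bundle (header-only tables)
#'
#' @param schema A [sis_schema()].
#' @return An `sis_bundle` with zero taxa.
#' @export
empty_bundle <- function(schema = sis_schema()) {
  structure(empty_bundle_tables[c(sis_table_names, "points")],
            class = "sis_bundle", schema_version = schema$version)
}

#' @export
print.sis_bundle <- function(x, ...) {
  cat("<sis_bundle> ", nrow(x$taxonomy), " taxa; rows per table: ",
      paste(sprintf("%s=%d", names(x), vapply(x, nrow, integer(1))),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Validate a SIS bundle
#'
#' Mirrors the upload service's validation checks: referential integrity of
#' `internal_taxon_id` against the taxonomy table, exactly one taxonomy and
#' one assessments row per taxon, and category fixed to LC.
#'
#' @param bundle An `sis_bundle`.
#' @return Character vector of violations; empty when valid.
#' @export
validate_bundle <- function(bundle) {
  violations <- character()
  keys <- bundle$taxonomy$internal_taxon_id
  if (anyDuplicated(keys)) {
    dup <- unique(keys[duplicated(keys)])
    violations <- c(violations, paste0(
      "taxonomy: duplicate internal_taxon_id ", paste(dup, collapse = ", ")
    ))
  }
  for (tbl in c(setdiff(sis_table_names, "taxonomy"), "points")) {
    orphan <- setdiff(unique(bundle[[tbl]]$internal_taxon_id), keys)
    if (length(orphan)) {
      violations <- c(violations, paste0(
        tbl, ": internal_taxon_id not in taxonomy: ",
        paste(orphan, collapse = ", ")
      ))
    }
  }
  ass <- bundle$assessments
  dup <- unique(ass$internal_taxon_id[duplicated(ass$internal_taxon_id)])
  if (length(dup)) {
    violations <- c(violations, paste0(
      "assessments: duplicate internal_taxon_id ", paste(dup, collapse = ", ")
    ))
  }
  missing_ass <- setdiff(keys, ass$internal_taxon_id)
  if (length(missing_ass)) {
    violations <- c(violations, paste0(
      "assessments: missing row for internal_taxon_id ",
      paste(missing_ass, collapse = ", ")
    ))
  }
  not_lc <- unique(ass$internal_taxon_id[ass$RedListCategory != "LC"])
  if (length(not_lc)) {
    violations <- c(violations, paste0(
      "assessments: category is not LC for internal_taxon_id ",
      paste(not_lc, collapse = ", ")
    ))
  }
  violations
}

#' Write a SIS bundle to disk
#'
#' Writes the seven assessment CSVs, zips them into one archive, and writes
#' the point-distribution CSV alongside (it is downloaded separately, not
#' part of the zip). All files are UTF-8, comma-delimited, quoted where
#' needed.
#'
#' @param bundle An `sis_bundle`.
#' @param out_dir Output directory (created if needed).
#' @param zip_name Name of the zip archive.
#' @return Invisibly, a list with `zip`, `tables` (named CSV paths) and
#'   `points` path.
#' @export
write_bundle <- function(bundle, out_dir, zip_name = "sis_bundle.zip") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (tbl in sis_table_names) {
    p <- file.path(out_dir, paste0(tbl, ".csv"))
    readr::write_csv(bundle[[tbl]], p, progress = FALSE)
    paths[[tbl]] <- p
  }
  points_path <- file.path(out_dir, "points.csv")
  readr::write_csv(bundle$points, points_path, progress = FALSE)
  zip_path <- file.path(out_dir, zip_name)
  write_zip(paths, zip_path, names = paste0(sis_table_names, ".csv"))
  invisible(list(zip = zip_path, tables = paths, points = points_path))
}

#' Read a SIS bundle back from disk
#'
#' @param dir Directory holding the seven table CSVs and `points.csv`, as
#'   written by [write_bundle()].
#' @return An `sis_bundle`.
#' @export
read_bundle <- function(dir) {
  read_tbl <- function(name, types) {
    readr::read_csv(file.path(dir, paste0(name, ".csv")), col_types = types,
                    progress = FALSE)
  }
  bundle <- list(
    allfields = read_tbl("allfields", "ddddd"),
    assessments = read_tbl("assessments", "dccccc"),
    countries = read_tbl("countries", "dccccc"),
    credits = read_tbl("credits", "dcc"),
    habitats = read_tbl("habitats", "dcc"),
    plantspecific = read_tbl("plantspecific", "dc"),
    taxonomy = read_tbl("taxonomy", "dcccc"),
    points = read_tbl("points", "dcddccc")
  )
  bundle <- bundle[c(sis_table_names, "points")]
  structure(bundle, class = "sis_bundle",
            schema_version = sis_schema()$version)
}
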