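lc_taxa <- function(n = 1, codes = list("BER")) {
  withr::with_seed(n, {
    tibble::tibble(
      full_name = sprintf("Synthetica species%02d", seq_len(n)),
      authorship = "L.", family = "Syntheticaceae",
      powo_id = sprintf("powo:%d", seq_len(n)),
      eoo_km2 = 50000, aoo_km2 = 5000, record_count = 100L, tdwg_count = 6L,
      least_concern = TRUE,
      range = lapply(seq_len(n), function(i) {
        native_range(sprintf("powo:%d", i),
                     codes[[((i - 1) %% length(codes)) + 1]])
      }),
      points = lapply(seq_len(n), function(i) {
        tibble::tibble(longitude = stats::runif(3, -64.9, -64.6),
                       latitude = stats::runif(3, 32.2, 32.4))
      })
    )
  })
}

test_that("a one-taxon bundle carries taxonomy, LC category and countries", {
  b <- build_bundle(lc_taxa(1))
  expect_identical(nrow(b$taxonomy), 1L)
  expect_equal(b$taxonomy$genus, "Synthetica")
  expect_equal(b$assessments$RedListCategory, "LC")
  expect_match(b$assessments$RedListRationale, "Synthetica species01")
  expect_gte(nrow(b$countries), 1L)
  expect_equal(b$countries$country, "Bermuda")
  expect_equal(b$countries$l3_code, "BER")
  expect_identical(validate_bundle(b), character())
})

test_that("ids are sequential from 1 and every table's keys stay in range", {
  b <- build_bundle(lc_taxa(2, codes = list("BER", c("ANG", "ZAM"))))
  expect_equal(b$taxonomy$internal_taxon_id, c(1, 2))
  for (tbl in names(b)) {
    expect_true(all(b[[tbl]]$internal_taxon_id %in% c(1, 2)), label = tbl)
  }
  # one-to-many: second taxon has two country rows
  expect_identical(sum(b$countries$internal_taxon_id == 2), 2L)
})

test_that("codes absent from the country lookup fall back to the code", {
  taxa <- lc_taxa(1, codes = list("QQQ"))
  b <- build_bundle(taxa)
  expect_equal(b$countries$country, "QQQ")
})

test_that("non-LC taxa are rejected with their names in the message", {
  taxa <- lc_taxa(1)
  taxa$least_concern <- FALSE
  expect_error(build_bundle(taxa), "Synthetica species01")
})

test_that("an empty bundle is valid and writes seven header-only CSVs", {
  b <- empty_bundle()
  expect_identical(validate_bundle(b), character())
  out <- withr::local_tempdir()
  paths <- write_bundle(b, out)
  expect_length(paths$tables, 7L)
  for (p in paths$tables) {
    expect_identical(nrow(readr::read_csv(p, show_col_types = FALSE)), 0L)
  }
  listing <- utils::unzip(paths$zip, list = TRUE)
  expect_setequal(listing$Name,
                  paste0(c("allfields", "assessments", "countries", "credits",
                           "habitats", "plantspecific", "taxonomy"), ".csv"))
})

test_that("bundles round-trip through write and read identically", {
  b <- build_bundle(lc_taxa(3, codes = list("BER", "ANG", c("ZAM", "MOZ"))))
  out <- withr::local_tempdir()
  write_bundle(b, out)
  back <- read_bundle(out)
  for (tbl in names(b)) {
    expect_equal(back[[tbl]], b[[tbl]], label = tbl, ignore_attr = TRUE)
  }
})

test_that("zip members are extractable and byte-identical to the CSVs", {
  b <- build_bundle(lc_taxa(2))
  out <- withr::local_tempdir()
  paths <- write_bundle(b, out)
  ex <- withr::local_tempdir()
  utils::unzip(paths$zip, exdir = ex)
  for (tbl in names(paths$tables)) {
    orig <- readBin(paths$tables[[tbl]], "raw",
                    file.info(paths$tables[[tbl]])$size)
    got <- readBin(file.path(ex, paste0(tbl, ".csv")), "raw",
                   file.info(file.path(ex, paste0(tbl, ".csv")))$size)
    expect_identical(got, orig, label = tbl)
  }
})

test_that("validation flags orphan keys and duplicate single-row entries", {
  b <- build_bundle(lc_taxa(1))
  b$habitats <- dplyr::bind_rows(
    b$habitats, tibble::tibble(internal_taxon_id = 99,
                               GeneralHabitats = "1",
                               GeneralHabitatsName = "Forest")
  )
  v <- validate_bundle(b)
  expect_length(v, 1L)
  expect_match(v, "habitats")
  expect_match(v, "99")

  b2 <- build_bundle(lc_taxa(1))
  b2$taxonomy <- dplyr::bind_rows(b2$taxonomy, b2$taxonomy)
  expect_true(any(grepl("duplicate", validate_bundle(b2))))

  b3 <- build_bundle(lc_taxa(1))
  b3$assessments$RedListCategory <- "VU"
  expect_true(any(grepl("not LC", validate_bundle(b3))))
})

test_that("random generated bundles validate and round-trip", {
  code_pool <- c("BER", "ANG", "ZAM", "MOZ", "KEN", "TAN", "QQA")
  withr::with_seed(83, {
    for (i in 1:20) {
      n <- sample(0:6, 1)
      codes <- lapply(seq_len(max(n, 1)), function(j) {
        sample(code_pool, sample(1:3, 1))
      })
      taxa <- lc_taxa(n, codes = codes)
      b <- if (n == 0) empty_bundle() else build_bundle(taxa)
      expect_identical(validate_bundle(b), character())
      out <- withr::local_tempdir()
      write_bundle(b, out)
      back <- read_bundle(out)
      for (tbl in names(b)) {
        expect_equal(back[[tbl]], b[[tbl]], ignore_attr = TRUE)
      }
    }
  })
})
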