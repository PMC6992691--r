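metrics_row <- function(eoo, aoo, rec, tdwg, warning = "") {
  tibble::tibble(eoo_km2 = eoo, aoo_km2 = aoo, record_count = rec,
                 tdwg_count = tdwg, warning = warning)
}

test_that("default thresholds and limits match the documented values", {
  th <- lc_thresholds()
  expect_equal(th$eoo_km2, 30000)
  expect_equal(th$aoo_km2, 3000)
  expect_equal(th$record_count, 75)
  expect_equal(th$tdwg_count, 5)
  cfg <- run_config("batch")
  expect_identical(cfg$occ_limit, 3000L)
  expect_identical(cfg$batch_limit, 100L)
  expect_equal(cfg$cell_km, 10)
})

test_that("a metric exactly at its threshold passes (meets or exceeds)", {
  g <- evaluate(metrics_row(30000, 3000, 75, 5))
  expect_true(all(g$eoo_pass, g$aoo_pass, g$records_pass, g$tdwg_pass))
  expect_true(g$least_concern)

  g2 <- evaluate(metrics_row(29999.9, 3000, 75, 5))
  expect_false(g2$eoo_pass)
  expect_false(g2$least_concern)
})

test_that("a warning forces not-LC regardless of the metrics", {
  g <- evaluate(metrics_row(1e6, 1e5, 1000, 20, warning = "no points"))
  expect_false(g$least_concern)
  expect_identical(g$warning, "no points")

  g0 <- evaluate(metrics_row(0, 0, 0L, 0L, warning = "no points"))
  expect_false(g0$least_concern)
})

test_that("classification grid: inclusivity, warning dominance, monotonicity", {
  # exhaustive over a grid of metric values around each threshold x warning
  th <- lc_thresholds()
  eoo_vals <- c(0, 29999, 30000, 60000)
  aoo_vals <- c(0, 2999, 3000, 6000)
  rec_vals <- c(0, 74, 75, 200)
  tdwg_vals <- c(0, 4, 5, 9)
  grid <- expand.grid(eoo = eoo_vals, aoo = aoo_vals, rec = rec_vals,
                      tdwg = tdwg_vals, warn = c("", "w"),
                      stringsAsFactors = FALSE)
  got <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got[i] <- evaluate(metrics_row(g$eoo, g$aoo, g$rec, g$tdwg,
                                   g$warn))$least_concern
    expected <- g$eoo >= 30000 && g$aoo >= 3000 && g$rec >= 75 &&
      g$tdwg >= 5 && !nzchar(g$warn)
    expect_identical(got[i], expected)
  }
  # monotone: raising a threshold never flips FALSE -> TRUE
  rows <- tibble::tibble(
    full_name = sprintf("sp%d", seq_len(nrow(grid))), powo_id = "p",
    eoo_km2 = grid$eoo, aoo_km2 = grid$aoo, record_count = grid$rec,
    tdwg_count = grid$tdwg, warning = grid$warn
  )
  base <- classify_batch(rows, th)
  for (bump in list(lc_thresholds(eoo_km2 = 40000),
                    lc_thresholds(aoo_km2 = 4000),
                    lc_thresholds(record_count = 100),
                    lc_thresholds(tdwg_count = 7))) {
    bumped <- classify_batch(rows, bump)
    expect_true(all(bumped$least_concern <= base$least_concern))
  }
})

test_that("LC counts are non-increasing along a rising threshold sweep", {
  withr::with_seed(71, {
    rows <- tibble::tibble(
      full_name = sprintf("sp%03d", 1:60), powo_id = "p",
      eoo_km2 = stats::rlnorm(60, log(30000), 1),
      aoo_km2 = stats::rlnorm(60, log(3000), 1),
      record_count = stats::rpois(60, 75),
      tdwg_count = stats::rpois(60, 5),
      warning = ""
    )
  })
  for (param in c("eoo_km2", "aoo_km2", "record_count", "tdwg_count")) {
    counts <- vapply(stats::quantile(rows[[param]], 0:10 / 10), function(t) {
      args <- list(30000, 3000, 75, 5)
      names(args) <- c("eoo_km2", "aoo_km2", "record_count", "tdwg_count")
      args[c("eoo_km2", "aoo_km2", "record_count", "tdwg_count")] <-
        list(1e-9, 1e-9, 1e-9, 1e-9)  # isolate the swept parameter
      args[[param]] <- max(t, 1e-9)
      sum(classify_batch(rows, do.call(lc_thresholds, args))$least_concern)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0), label = param)
  }
})

test_that("rerunning with new thresholds changes only the LC flags", {
  rows <- metrics_row(c(5e4, 1e3), c(5e3, 100), c(100L, 10L), c(6L, 1L))
  rows$full_name <- c("a", "b")
  rows$powo_id <- c("p1", "p2")
  r1 <- classify_batch(rows)
  r2 <- classify_batch(rows, lc_thresholds(eoo_km2 = 1e5))
  metric_cols <- c("full_name", "powo_id", "eoo_km2", "aoo_km2",
                   "record_count", "tdwg_count", "warning")
  expect_identical(r1[metric_cols], r2[metric_cols])
  expect_false(identical(r1$least_concern, r2$least_concern))
})

test_that("empty input classifies to an empty table with fixed columns", {
  out <- classify_batch(tibble::tibble())
  expect_identical(nrow(out), 0L)
  expect_named(out, c("full_name", "powo_id", "eoo_km2", "aoo_km2",
                      "record_count", "tdwg_count", "least_concern",
                      "warning"))
})

test_that("a 124-species table planted with 109 passers yields a 109/15 split", {
  withr::with_seed(124, {
    pass <- tibble::tibble(
      full_name = sprintf("lc%03d", 1:109), powo_id = "p",
      eoo_km2 = stats::runif(109, 30000, 3e6),
      aoo_km2 = stats::runif(109, 3000, 1e5),
      record_count = sample(75:2000, 109, replace = TRUE),
      tdwg_count = sample(5:40, 109, replace = TRUE),
      warning = ""
    )
    fail <- tibble::tibble(
      full_name = sprintf("nt%02d", 1:15), powo_id = "p",
      eoo_km2 = stats::runif(15, 0, 29999),
      aoo_km2 = stats::runif(15, 3000, 1e5),
      record_count = sample(75:2000, 15, replace = TRUE),
      tdwg_count = sample(5:40, 15, replace = TRUE),
      warning = ""
    )
  })
  out <- classify_batch(dplyr::bind_rows(pass, fail))
  expect_identical(sum(out$least_concern), 109L)
  expect_identical(sum(!out$least_concern), 15L)
})
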