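test_that("degenerate point sets give EOO 0 with a warning", {
  two <- points_set(c(0, 1), c(0, 1))
  eoo <- compute_eoo(two)
  expect_equal(as.numeric(eoo), 0)
  expect_match(attr(eoo, "warning"), "fewer than 3")

  # collinear in projected km space (degree-space lines do not project to
  # lines under the equal-area transform)
  collinear <- unproject_points(c(0, 50, 100, 150), c(0, 25, 50, 75),
                                flat_ctx)
  eoo2 <- compute_eoo(collinear, flat_ctx)
  expect_equal(as.numeric(eoo2), 0)
  expect_match(attr(eoo2, "warning"), "collinear")
})

test_that("a projected 100 km x 100 km square has EOO 10,000 km^2", {
  corners <- unproject_points(c(0, 100, 100, 0), c(0, 0, 100, 100), flat_ctx)
  eoo <- compute_eoo(corners, flat_ctx)
  expect_equal(as.numeric(eoo), 10000, tolerance = 1e-9)
})

test_that("hull area matches the brute-force hull oracle on random sets", {
  withr::with_seed(41, {
    for (case in 1:25) {
      n <- sample(3:40, 1)
      x <- stats::runif(n, -500, 500)
      y <- stats::runif(n, -500, 500)
      pts <- unproject_points(x, y, flat_ctx)
      got <- as.numeric(compute_eoo(pts, flat_ctx))
      expected <- oracle_hull_area(x, y)
      expect_equal(got, expected, tolerance = 1e-6)
    }
  })
})

test_that("adding a point never decreases the hull area", {
  withr::with_seed(43, {
    x <- stats::runif(15, -300, 300)
    y <- stats::runif(15, -300, 300)
    for (i in 5:15) {
      a_small <- as.numeric(compute_eoo(
        unproject_points(x[1:(i - 1)], y[1:(i - 1)], flat_ctx), flat_ctx))
      a_big <- as.numeric(compute_eoo(
        unproject_points(x[1:i], y[1:i], flat_ctx), flat_ctx))
      expect_gte(a_big, a_small - 1e-9)
    }
  })
})

test_that("a tight cluster occupies a single default AOO cell: 100 km^2", {
  cloud <- gen_cloud(20, -10, dispersion_km = 1, n = 5, seed = 5)
  expect_equal(as.numeric(compute_aoo(cloud)), 100)
})

test_that("AOO equals brute-force distinct-cell count times cell area", {
  withr::with_seed(47, {
    for (case in 1:25) {
      n <- sample(1:100, 1)
      x <- stats::runif(n, -200, 200)
      y <- stats::runif(n, -200, 200)
      pts <- unproject_points(x, y, flat_ctx)
      for (cell in c(2, 10)) {
        got <- as.numeric(compute_aoo(pts, flat_ctx, cell_km = cell))
        expect_equal(got, oracle_cell_count(x, y, cell) * cell^2)
      }
    }
  })
})

test_that("AOO is unchanged by within-cell jitter and bounded by records", {
  withr::with_seed(53, {
    cell <- 10
    n <- 30
    # cell centres (origin-centred grid), then jitter inside each cell
    cx <- sample(-20:20, n, replace = TRUE) * cell
    cy <- sample(-20:20, n, replace = TRUE) * cell
    jx <- stats::runif(n, -cell / 2 + 1e-6, cell / 2 - 1e-6)
    jy <- stats::runif(n, -cell / 2 + 1e-6, cell / 2 - 1e-6)
    base <- as.numeric(compute_aoo(
      unproject_points(cx, cy, flat_ctx), flat_ctx, cell))
    jittered <- as.numeric(compute_aoo(
      unproject_points(cx + jx, cy + jy, flat_ctx), flat_ctx, cell))
    expect_equal(jittered, base)
    expect_gte(base, cell^2)
    expect_lte(base, n * cell^2)
  })
})

test_that("halving the cell size at most quadruples the occupied cell count", {
  withr::with_seed(59, {
    for (case in 1:10) {
      n <- sample(5:80, 1)
      pts <- unproject_points(stats::runif(n, -300, 300),
                              stats::runif(n, -300, 300), flat_ctx)
      for (cell in c(20, 10)) {
        coarse <- as.numeric(compute_aoo(pts, flat_ctx, cell)) / cell^2
        fine <- as.numeric(compute_aoo(pts, flat_ctx, cell / 2)) /
          (cell / 2)^2
        expect_lte(fine, 4 * coarse)
        expect_gte(fine, coarse)
      }
    }
  })
})

test_that("record and region counts follow set semantics", {
  expect_identical(count_records(points_set(numeric(), numeric())), 0L)
  expect_identical(count_records(points_set(1, 2)), 1L)
  dup <- points_set(c(1, 1, 2, 2, 3), c(1, 1, 2, 2, 3))
  expect_identical(count_records(dup), 3L)

  expect_identical(count_tdwg(as_filtered(dup, c("AAA", "AAB"))), 2L)
  expect_identical(count_tdwg(as_filtered(dup, character())), 0L)
})

test_that("region count reflects occupied regions in the toy grid", {
  store <- gen_toy_regions(5)
  # points in 3 of the 5 regions
  s <- points_set(c(5, 15, 45), c(5, 5, 5))
  f <- filter_to_native(s, native_range("p", names(store$regions)), store)
  expect_identical(count_tdwg(f), 3L)
})

test_that("compute_metrics composes the four statistics consistently", {
  store <- gen_toy_regions(2)
  cloud <- gen_cloud(5, 5, dispersion_km = 1, n = 8, seed = 9)
  f <- filter_to_native(clean_records(cloud),
                        native_range("p", c("AAA", "AAB")), store)
  m <- compute_metrics(f)
  expect_equal(m$aoo_km2, 100)
  expect_lt(m$eoo_km2, 100)
  expect_identical(m$record_count, count_records(f))
  expect_identical(m$tdwg_count, 1L)
  expect_identical(m$warning, "")
})

test_that("no retained points yields all-zero metrics with a warning", {
  f <- as_filtered(points_set(numeric(), numeric()))
  m <- compute_metrics(f)
  expect_equal(m$eoo_km2, 0)
  expect_equal(m$aoo_km2, 0)
  expect_identical(m$record_count, 0L)
  expect_identical(m$tdwg_count, 0L)
  expect_match(m$warning, "no georeferenced points")
})

test_that("metrics are invariant to point order", {
  withr::with_seed(61, {
    lon <- stats::runif(20, 0, 9)
    lat <- stats::runif(20, 0, 9)
  })
  store <- gen_toy_regions(1)
  perm <- sample(20)
  f1 <- filter_to_native(points_set(lon, lat), native_range("p", "AAA"),
                         store)
  f2 <- filter_to_native(points_set(lon[perm], lat[perm]),
                         native_range("p", "AAA"), store)
  ctx <- projection_context(f1)
  m1 <- compute_metrics(f1, ctx)
  m2 <- compute_metrics(f2, ctx)
  expect_equal(m1$eoo_km2, m2$eoo_km2)
  expect_equal(m1$aoo_km2, m2$aoo_km2)
  expect_identical(m1$record_count, m2$record_count)
})
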