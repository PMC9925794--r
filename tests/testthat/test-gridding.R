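test_that("grid construction matches the arithmetic of extent and resolution", {
  g <- build_grid(c(-180, -90, 180, 90), 0.5)
  expect_equal(g$n_cols * g$n_rows, 720L * 360L)
  g4 <- build_grid(c(0, 0, 1, 1), 0.5)
  expect_equal(length(g4$mask), 4L)
  expect_equal(g4$mask, 0:3)
  # mask polygon inside a single cell keeps exactly that cell
  gm <- build_grid(c(0, 0, 1, 1), 0.5, mask_polygons = geom_rect(0.6, 0.6, 0.9, 0.9))
  expect_equal(gm$mask, 3L)
  expect_error(build_grid(c(0, 0, 1, 1), 0.5, mask_polygons = geom_rect(5, 5, 6, 6)),
               "no grid cell")
})

test_that("non-aligned extents snap outward to whole cells", {
  g <- build_grid(c(0.2, 0.1, 0.9, 0.8), 0.5)
  expect_equal(g$origin, c(0, 0))
  expect_equal(c(g$n_cols, g$n_rows), c(2L, 2L))
})

test_that("cell areas follow the spherical zone formula", {
  g <- build_grid(c(-180, -90, 180, 90), 0.5)
  eq_cell <- cell_from_point(g, 0.25, 0.25)
  expect_equal(cell_area_km2(g, eq_cell), 3091.047, tolerance = 1e-4)
  hi_cell <- cell_from_point(g, 0.25, 59.75)
  expect_equal(cell_area_km2(g, hi_cell) / cell_area_km2(g, eq_cell),
               cos(59.75 * pi / 180), tolerance = 0.01)
  expect_equal(sum(cell_area_km2(g)), 4 * pi * 6371.0088^2, tolerance = 0.001)
})

test_that("rasterization rules agree on exact-cell polygons and diverge on corners", {
  g <- build_grid(c(0, 0, 2, 2), 0.5)
  one_cell <- list(croc_range("S1", geom_rect(0.5, 0.5, 1, 1)))
  for (rule in c("any_intersection", "centroid_within", "min_fraction")) {
    m <- rasterize_ranges(one_cell, g, rule = rule)
    expect_equal(rownames(m)[m[, "S1"] == 1], as.character(cell_from_point(g, 0.75, 0.75)),
                 info = rule)
  }
  # small square centered on the corner shared by 4 cells
  corner <- list(croc_range("S1", geom_rect(0.9, 0.9, 1.1, 1.1)))
  m_any <- rasterize_ranges(corner, g, rule = "any_intersection")
  expect_equal(sum(m_any), 4L)
  m_cen <- rasterize_ranges(corner, g, rule = "centroid_within")
  expect_lte(sum(m_cen), 1L)
  # two species with disjoint one-cell ranges -> identity-like matrix
  two <- list(croc_range("A", geom_rect(0, 0, 0.5, 0.5)),
              croc_range("B", geom_rect(1.5, 1.5, 2, 2)))
  m2 <- rasterize_ranges(two, g)
  expect_equal(colSums(m2), c(A = 1, B = 1))
  expect_equal(sum(m2["0", ]), 1)
  # species outside the grid dropped with warning
  expect_warning(
    m3 <- rasterize_ranges(c(two, list(croc_range("C", geom_rect(30, 30, 31, 31)))), g),
    "dropping species")
  expect_equal(colnames(m3), c("A", "B"))
})

test_that("any_intersection occupancy contains centroid_within occupancy", {
  # convex ranges, where the centroid is guaranteed inside the range
  set.seed(11)
  g <- build_grid(c(0, -10, 20, 10), 0.5)
  r <- lapply(1:8, function(i) {
    x0 <- runif(1, 0, 15); y0 <- runif(1, -10, 5)
    croc_range(paste0("S", i),
               geom_rect(x0, y0, x0 + runif(1, 0.3, 4), y0 + runif(1, 0.3, 4)))
  })
  m_any <- rasterize_ranges(r, g)
  m_cen <- suppressWarnings(rasterize_ranges(r, g, rule = "centroid_within"))
  for (sp in colnames(m_cen))
    expect_true(all(m_any[, sp] >= m_cen[, sp]))
})

test_that("PA coverage fractions are exact and use union semantics", {
  g <- build_grid(c(0, 0, 1, 1), 0.5)
  west_half <- geom_rect(0, 0, 0.25, 0.5)  # west half of cell 0
  cov <- pa_coverage(list(west_half), g)
  expect_equal(unname(cov["0"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(cov["3"]), 0)
  expect_equal(unname(pa_coverage(list(), g)), rep(0, 4))
  full <- pa_coverage(list(geom_rect(0, 0, 1, 1)), g)
  expect_equal(unname(full), rep(1, 4), tolerance = 1e-9)
  # splitting one PA into two overlapping halves changes nothing
  split_cov <- pa_coverage(list(geom_rect(0, 0, 0.15, 0.5),
                                geom_rect(0.1, 0, 0.25, 0.5)), g)
  expect_equal(split_cov, cov, tolerance = 1e-9)
})

test_that("raster aggregation to the grid handles the standard cases", {
  g <- build_grid(c(0, 0, 1, 1), 0.5)
  # raster at grid resolution -> identity
  v <- stats::setNames(c(1, 2, 3, 4), as.character(0:3))
  ras <- grid_values_to_raster(v, g)
  expect_equal(aggregate_raster_to_grid(ras, g), v)
  # 2x2 pixels per cell with values 1..4 -> mean 2.5
  fine <- structure(list(values = matrix(c(1, 3, 2, 4), 2, 2),
                         xll = 0, yll = 0.5, cellsize = 0.25, nodata = -9999),
                    class = "croc_raster")
  agg <- aggregate_raster_to_grid(fine, g)
  expect_equal(unname(agg["2"]), 2.5)
  expect_true(all(is.na(agg[c("0", "1", "3")])))
  # constant raster stays constant under mean
  const <- grid_values_to_raster(stats::setNames(rep(7, 4), as.character(0:3)), g)
  expect_equal(unname(aggregate_raster_to_grid(const, g)), rep(7, 4))
})
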