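test_that("circular kernel matches offset enumeration", {
  # radius = cell: plus-shaped 3x3 with 5 cells
  k1 <- circular_kernel(30, 30)
  expect_equal(dim(k1), c(3, 3))
  expect_equal(sum(k1), 5)
  expect_equal(k1, matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3))
  # sub-cell radius: centre only
  expect_equal(circular_kernel(15, 30), matrix(1, 1, 1))
  # radius = 2 cells: 5x5 with 13 cells (enumerated: offsets with di^2+dj^2 <= 4)
  k2 <- circular_kernel(60, 30)
  expect_equal(dim(k2), c(5, 5))
  expect_equal(sum(k2), 13)
  brute <- outer(-2:2, -2:2, function(di, dj) (di^2 + dj^2 <= 4) * 1)
  expect_equal(k2, brute)
  expect_error(circular_kernel(10, 30), class = "scenhab_error_parameter")
})

test_that("focal proportions handle uniform and tiny grids", {
  spec <- grid_spec(5, 5, 30)
  g <- habitat_grid(matrix(1L, 5, 5), spec, c(a = 1, b = 2))
  st <- focal_proportions(g, radius = 60)
  expect_true(all(st$layers$a == 1))
  expect_true(all(st$layers$b == 0))

  g2 <- habitat_grid(matrix(c(1L, 1L, 2L, 1L), 2, 2), grid_spec(2, 2, 30), c(a = 1, b = 2))
  st2 <- focal_proportions(g2, radius = 1000) # spans the whole grid
  expect_true(all(abs(st2$layers$a - 0.75) < 1e-12))
  expect_true(all(abs(st2$layers$b - 0.25) < 1e-12))
})

test_that("focal proportions equal the brute-force window oracle", {
  g <- make_test_grid(n = 20, k = 3, seed = 42)
  radius <- 3 * 30
  st <- focal_proportions(g, radius = radius)
  for (code in 1:3) {
    oracle <- oracle_focal_proportion(g$classes, code, radius, 30)
    expect_equal(st$layers[[paste0("class_", code)]], oracle, tolerance = 1e-9)
  }
})

test_that("focal proportions handle nodata and grid edges consistently", {
  withr::with_seed(9, {
    classes <- matrix(sample.int(3, 15 * 15, replace = TRUE), 15, 15)
    classes[sample.int(225, 20)] <- NA
  })
  g <- habitat_grid(classes, grid_spec(15, 15, 30), c(a = 1, b = 2, c = 3))
  st <- focal_proportions(g, radius = 75)
  for (code in 1:3) {
    oracle <- oracle_focal_proportion(classes, code, 75, 30)
    expect_equal(st$layers[[code]], oracle, tolerance = 1e-9)
  }
  # proportions sum to 1 at every defined cell, including edges
  total <- Reduce(`+`, st$layers)
  expect_true(all(abs(total[!is.na(total)] - 1) < 1e-9))
})

test_that("focal proportions are equivariant under class relabelling", {
  g <- make_test_grid(n = 12, k = 3, seed = 5)
  st <- focal_proportions(g, radius = 90)
  # permute codes 1->2->3->1
  perm <- c(2L, 3L, 1L)
  g2 <- habitat_grid(
    matrix(perm[g$classes], 12, 12), g$spec,
    c(class_1 = 1, class_2 = 2, class_3 = 3)
  )
  st2 <- focal_proportions(g2, radius = 90)
  for (code in 1:3) {
    expect_equal(st2$layers[[perm[code]]], st$layers[[code]])
  }
})

test_that("habitat grids round-trip through ASCII files", {
  g <- make_test_grid(n = 8, k = 4, seed = 2, cell_size = 28.5)
  path <- withr::local_tempfile(fileext = ".asc")
  write_habitat_grid(g, path)
  g2 <- read_habitat_grid(path)
  expect_equal(g2$classes, g$classes)
  expect_equal(g2$spec$cell_size, g$spec$cell_size)
  expect_equal(g2$spec$origin, g$spec$origin)
  expect_equal(g2$legend, g$legend)

  # continuous round-trip
  cg <- continuous_grid(matrix(runif(64), 8, 8), g$spec, "alt")
  cpath <- withr::local_tempfile(fileext = ".asc")
  write_continuous_grid(cg, cpath)
  cg2 <- read_continuous_grid(cpath, name = "alt")
  expect_equal(cg2$values, cg$values, tolerance = 1e-8)
})

test_that("small explicit rasters read back row-major with format errors", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c(
    "ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
    "cellsize 30", "NODATA_value -9999",
    "1 1", "2 2"
  ), path)
  g <- read_habitat_grid(path, legend = c(a = 1, b = 2))
  expect_equal(g$classes, matrix(c(1L, 2L, 1L, 2L), 2, 2))

  # float band is rejected for habitat grids
  fpath <- withr::local_tempfile(fileext = ".asc")
  writeLines(c(
    "ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
    "cellsize 30", "NODATA_value -9999",
    "1 1.5", "2 2"
  ), fpath)
  expect_error(read_habitat_grid(fpath, legend = c(a = 1, b = 2)),
    class = "scenhab_error_format"
  )

  # missing geotransform header
  bpath <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "1 1", "2 2", "x y", "1 1", "1 1", "2 2"), bpath)
  suppressWarnings( # coercion warnings precede the format error
    expect_error(read_habitat_grid(bpath, legend = c(a = 1, b = 2)),
      class = "scenhab_error_format"
    )
  )
})

test_that("point-to-cell mapping uses half-open upper-left cells", {
  spec <- grid_spec(4, 4, 10, origin = c(100, 200))
  rc <- points_to_cells(spec, c(100, 109.999, 110, 139.999, 140), rep(195, 5))
  expect_equal(rc$col, c(1L, 1L, 2L, 4L, NA))
  expect_equal(rc$row, c(1L, 1L, 1L, 1L, NA))
  # cell centres invert the mapping
  ctr <- cell_centers(spec, 2, 3)
  rc2 <- points_to_cells(spec, ctr$x, ctr$y)
  expect_equal(c(rc2$row, rc2$col), c(2L, 3L))
})
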