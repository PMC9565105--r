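test_that("annual cubes roundtrip through ASCII grids", {
  set.seed(11)
  v <- array(runif(3 * 4 * 4), c(3, 4, 4))
  tr <- list(xllcorner = 100.5, yllcorner = -20, cellsize = 0.25)
  cube <- annual_cube(v, 2000:2002, transform = tr)
  dir <- withr::local_tempdir()
  paths <- write_annual_cube(cube, dir, "ndvi")
  back <- read_annual_cube(paths, 2000:2002)
  expect_equal(back$values, cube$values)
  expect_identical(back$years, cube$years)
  expect_equal(back$transform, tr)
})

test_that("mismatched grids and length mismatches are hard errors", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.asc"); p2 <- file.path(dir, "b.asc")
  write_ascii_grid(matrix(1, 4, 4), p1)
  write_ascii_grid(matrix(1, 5, 4), p2)
  expect_error(read_annual_cube(c(p1, p2), 2000:2001), "b\\.asc")
  expect_error(read_annual_cube(p1, 2000:2001), "differ in length")
  p3 <- file.path(dir, "c.asc")
  write_ascii_grid(matrix(1, 4, 4), p3,
                   transform = list(xllcorner = 9, yllcorner = 0, cellsize = 1))
  expect_error(read_annual_cube(c(p1, p3), 2000:2001), "geometry")
})

test_that("a pixel nodata in any year is masked everywhere", {
  dir <- withr::local_tempdir()
  m <- matrix(0.5, 3, 3)
  paths <- file.path(dir, sprintf("y%d.asc", 1:3))
  write_ascii_grid(m, paths[1])
  m2 <- m; m2[2, 2] <- NA
  write_ascii_grid(m2, paths[2])
  write_ascii_grid(m, paths[3])
  cube <- read_annual_cube(paths, 2000:2002)
  expect_identical(sum(cube$nodata_mask), 1L)
  expect_true(cube$nodata_mask[2, 2])
  expect_true(all(is.na(cube$values[, 2, 2])))
})

test_that("growing-season compositing averages only April-October layers", {
  nr <- 2; nc <- 2
  dates <- as.Date(c("2000-03-25", "2000-04-10", "2000-07-01", "2000-10-31",
                     "2001-04-01", "2001-11-15", "2001-08-15"))
  layers <- array(NA_real_, c(length(dates), nr, nc))
  layers[1, , ] <- 0.0   # March: excluded
  layers[2, , ] <- 0.2
  layers[3, , ] <- 0.4
  layers[4, , ] <- 0.6   # Oct 31: included
  layers[5, , ] <- 0.5
  layers[6, , ] <- 0.9   # November: excluded
  layers[7, , ] <- 0.5
  cube <- composite_growing_season(layers, dates)
  expect_equal(cube$years, 2000:2001)
  expect_equal(cube$values[1, 1, 1], mean(c(0.2, 0.4, 0.6)))
  expect_equal(cube$values[2, 1, 1], 0.5)

  # March-only layer in 2000 with value 0.0 plus one April layer 0.6:
  # excluded layer does not dilute the composite
  two <- array(NA_real_, c(2, 1, 1))
  two[1, , ] <- 0.0; two[2, , ] <- 0.6
  c2 <- composite_growing_season(two, as.Date(c("2000-03-25", "2000-04-10")))
  expect_equal(c2$values[1, 1, 1], 0.6)

  # order invariance
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  cube_p <- composite_growing_season(layers[perm, , , drop = FALSE], dates[perm])
  expect_equal(cube_p$values, cube$values)

  # a year with no in-window layer is a gap -> error
  expect_error(
    composite_growing_season(two, as.Date(c("2000-03-25", "2001-04-10"))),
    "gap-free")
})

test_that("validity mask excludes sparse vegetation by period-mean NDVI", {
  v <- array(0.5, c(3, 2, 2))
  v[, 1, 1] <- 0.05                      # barren: excluded
  v[, 1, 2] <- 0.10                      # boundary: inclusive
  v[, 2, 1] <- c(0.05, 0.10, 0.18)       # mean 0.11: valid under period mean
  cube <- annual_cube(v, 2000:2002)
  mask <- build_valid_mask(cube)
  expect_identical(mask, matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2))
  # per-year rule excludes the dipping pixel
  mask_y <- build_valid_mask(cube, rule = "every_year")
  expect_false(mask_y[2, 1])
  expect_true(mask_y[1, 2])
  # all clear -> all TRUE
  expect_true(all(build_valid_mask(annual_cube(array(0.4, c(3, 2, 2)),
                                               2000:2002))))
  expect_warning(build_valid_mask(annual_cube(array(0.01, c(3, 2, 2)),
                                              2000:2002)),
                 "no valid pixels")
})

test_that("zonal summaries: mean, class fractions, histogram", {
  zones <- zone_mask(matrix(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L), 2, 4),
                     c(`1` = "GTGP", `2` = "GRP"))
  layer <- matrix(c(1, 2, 3, 4, 10, 30, 50, 90), 2, 4)
  zm <- zonal_summary(layer, zones, "mean")
  expect_equal(zm$mean[zm$zone == "GTGP"], 2.5)

  cls <- matrix(c("improve", "improve", "stable", "improve",
                  "stable", "stable", "stable", "improve"), 2, 4)
  zf <- zonal_summary(cls, zones, "class_fraction")
  g <- zf[zf$zone == "GTGP", ]
  expect_equal(g$fraction[g$class == "improve"], 3 / 4)
  expect_equal(g$fraction[g$class == "stable"], 1 / 4)
  for (z in unique(zf$zone)) {
    expect_equal(sum(zf$fraction[zf$zone == z]), 1, tolerance = 1e-12)
  }

  zh <- zonal_summary(layer, zones, "histogram", breaks = seq(0, 100, 20))
  expect_equal(zh$count[zh$zone == "GRP"], c(1L, 1L, 1L, 0L, 1L))

  expect_error(zonal_summary(layer, zones, "median"))
  # zone with zero valid pixels gets an NA row
  vm <- matrix(rep(c(TRUE, FALSE), each = 4), 2, 4)
  zm2 <- zonal_summary(layer, zones, "mean", valid_mask = vm)
  expect_true(is.na(zm2$mean[zm2$zone == "GRP"]))
})
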