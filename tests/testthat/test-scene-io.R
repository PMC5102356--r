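test_that("load_scene normalizes channels, derives pixel size, tolerates missing geolocation", {
  d <- withr::local_tempdir()
  # 4 x 3216 frame: footprint 121.8 m across the columns
  arr <- array(runif(4 * 3216 * 3), dim = c(4, 3216, 3))
  arr[1, 1, ] <- 1  # full-scale white pixel
  p <- file.path(d, "frame.png")
  png::writePNG(arr, p)
  sc <- load_scene(p, list(scene_id = "frame", footprint_width_m = 121.8))
  expect_s3_class(sc, "scene_image")
  expect_equal(sc$pixel_size_m, 121.8 / 3216, tolerance = 1e-12)
  expect_equal(unname(sc$pixels[1, 1, ]), c(1, 1, 1))
  expect_true(is.na(sc$lat) && is.na(sc$lon))  # absent coords, no error
  expect_true(all(sc$pixels >= 0 & sc$pixels <= 1))

  expect_error(load_scene(file.path(d, "nope.png")),
               class = "icehab_io_error")
  expect_error(load_scene(p, list(scene_id = "frame")),
               class = "icehab_validation_error")
  expect_error(load_scene(p, list(pixel_size_m = -1)),
               class = "icehab_validation_error")
})

test_that("standardize_resolution matches footprint arithmetic and preserves smooth content", {
  ps <- 121.8 / 3216
  arr <- array(0.5, dim = c(8, 3216, 3))
  sc <- scene_image(arr, pixel_size_m = ps)
  out <- standardize_resolution(sc, 0.04)
  expect_equal(ncol(out$pixels), 3045L)  # floor(121.8 / 0.04)
  expect_equal(out$pixel_size_m, 0.04)
  # constant image stays constant under bilinear resampling
  expect_equal(range(out$pixels), c(0.5, 0.5))

  # identity when already at target
  sc2 <- scene_image(array(runif(60), c(4, 5, 3)), pixel_size_m = 0.04)
  expect_identical(standardize_resolution(sc2, 0.04), sc2)

  # smooth gradient: mean intensity conserved within 1%
  g <- outer(seq(0.2, 0.8, length.out = 60), rep(1, 90))
  sm <- scene_image(array(rep(g, 3), c(60, 90, 3)), pixel_size_m = 0.1)
  res <- standardize_resolution(sm, 0.04)
  expect_lt(abs(mean(res$pixels) - mean(sm$pixels)) / mean(sm$pixels), 0.01)

  expect_error(standardize_resolution(sc2, -0.1),
               class = "icehab_validation_error")
})

test_that("enhance is identity at zero gains and fixes constant mid-gray", {
  sc <- scene_image(array(runif(300), c(10, 10, 3)), pixel_size_m = 0.04)
  id <- enhance_params(contrast_gain = 0, vibrance_gain = 0,
                       sharpen_amount = 0)
  expect_equal(enhance(sc, id)$pixels, sc$pixels)

  gray <- scene_image(array(0.5, c(12, 12, 3)), pixel_size_m = 0.04)
  out <- enhance(gray, enhance_params(contrast_gain = 0.5, vibrance_gain = 0,
                                      sharpen_amount = 0.8))
  expect_equal(out$pixels, gray$pixels)
})

test_that("unsharp masking raises an isolated bright pixel and depresses its ring", {
  arr <- array(0.4, c(11, 11, 3))
  arr[6, 6, ] <- 0.8
  sc <- scene_image(arr, pixel_size_m = 0.04)
  out <- enhance(sc, enhance_params(contrast_gain = 0, vibrance_gain = 0,
                                    sharpen_amount = 0.4, sharpen_sigma = 1))
  expect_gt(out$pixels[6, 6, 1], 0.8)     # center sharpened up
  expect_lt(out$pixels[6, 5, 1], 0.4)     # ring pushed down
  expect_lt(out$pixels[5, 6, 1], 0.4)
  expect_true(all(out$pixels >= 0 & out$pixels <= 1))
})

test_that("intensity is the channel mean and lies between the channel extremes", {
  v <- 0.37
  sc <- scene_image(array(v, c(5, 5, 3)), pixel_size_m = 0.04)
  expect_equal(rgb_to_intensity(sc)$values, matrix(v, 5, 5))

  red <- array(0, c(3, 3, 3)); red[, , 1] <- 1
  expect_equal(rgb_to_intensity(scene_image(red, 0.04))$values[1, 1], 1 / 3)

  px <- withr::with_seed(7, array(runif(6 * 8 * 3), c(6, 8, 3)))
  sc <- scene_image(px, pixel_size_m = 0.04)
  inten <- rgb_to_intensity(sc)$values
  expect_equal(inten, (px[, , 1] + px[, , 2] + px[, , 3]) / 3)
  expect_true(all(inten >= pmin(px[, , 1], px[, , 2], px[, , 3]) - 1e-12))
  expect_true(all(inten <= pmax(px[, , 1], px[, , 2], px[, , 3]) + 1e-12))
})

test_that("label rasters round-trip exactly and scene outputs are written", {
  d <- withr::local_tempdir()
  cm <- withr::with_seed(3, matrix(sample(0:3, 20 * 30, replace = TRUE),
                                   20, 30))
  attr(cm, "pixel_size_m") <- 0.12
  p <- file.path(d, "x_classes.png")
  write_label_raster(cm, p)
  back <- read_label_raster(p)
  expect_equal(matrix(back, 20, 30), matrix(cm, 20, 30))
  expect_equal(attr(back, "pixel_size_m"), 0.12)

  objects <- list(list(object_id = 1L, pixels = which(cm == 3L),
                       n_pixels = sum(cm == 3L), area_m2 = 2.5,
                       perimeter_m = 8, angularity = 1.4))
  st <- scene_stats(cm, objects, 0.12, scene_id = "x")
  paths <- write_outputs(cm, objects, st, d, scene_id = "x",
                         pixel_size_m = 0.12)
  expect_true(all(file.exists(paths)))
  gj <- jsonlite::read_json(paths[["vector"]])
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(gj$features[[1]]$properties$angularity, 1.4)
  blocker <- file.path(d, "afile")
  writeLines("x", blocker)
  expect_error(write_outputs(cm, objects, st, file.path(blocker, "sub")),
               class = "icehab_io_error")
})

test_that("GeoJSON polyline coordinates read back as a lon/lat matrix", {
  d <- withr::local_tempdir()
  p <- file.path(d, "terminus.geojson")
  jsonlite::write_json(list(
    type = "Feature",
    geometry = list(type = "LineString",
                    coordinates = list(c(-137.11, 58.87), c(-137.07, 58.87)))),
    p, auto_unbox = TRUE, digits = 8)
  m <- read_geojson_coords(p)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m[, "lat"], c(58.87, 58.87))
})
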