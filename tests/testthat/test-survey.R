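make_map <- function(nr, nc, water = 0, brash = 0, iceberg = 0) {
  cls <- ice_classes()
  m <- matrix(cls[["water"]], nr, nc)
  idx <- seq_len(nr * nc)
  stopifnot(water + brash + iceberg <= nr * nc)
  if (iceberg > 0) m[idx[seq_len(iceberg)]] <- cls[["iceberg"]]
  if (brash > 0) m[idx[iceberg + seq_len(brash)]] <- cls[["brash"]]
  m
}

test_that("scene statistics count classes exactly and sum to 100", {
  m <- make_map(20, 20)
  st <- scene_stats(m, list(), 0.04)
  expect_equal(c(st$iceberg_pct, st$brash_pct, st$water_pct), c(0, 0, 100))
  expect_true(is.na(st$mean_iceberg_size_m2))

  m2 <- make_map(20, 20, brash = 120, iceberg = 40)
  st2 <- scene_stats(m2, list(), 0.04)
  expect_equal(st2$iceberg_pct, 100 * 40 / 400)
  expect_equal(st2$brash_pct, 100 * 120 / 400)
  expect_equal(st2$iceberg_pct + st2$brash_pct + st2$water_pct, 100,
               tolerance = 1e-9)
  expect_equal(st2$iceberg_area_m2, 40 * 0.0016)

  objs <- list(list(area_m2 = 2, angularity = 1.2),
               list(area_m2 = 4, angularity = 1.8))
  st3 <- scene_stats(m2, objs, 0.04)
  expect_equal(st3$mean_iceberg_size_m2, 3)
  expect_equal(st3$mean_angularity, 1.5)
  cls <- ice_classes()
  expect_error(scene_stats(matrix(cls[["excluded"]], 4, 4), list(), 0.04),
               class = "icehab_validation_error")
})

test_that("distance to terminus is a point-to-polyline geodesic distance", {
  term <- cbind(lon = c(-137.05, -136.95), lat = c(58.86, 58.86))
  # a point on the constant-latitude segment sits within meters of the
  # geodesic joining the vertices
  expect_lt(distance_to_terminus(58.86, -137.0, term), 0.005)
  # 1000 m due north of the east-west segment
  d <- distance_to_terminus(58.86 + 1000 / 111320, -137.0, term)
  expect_equal(d, 1.0, tolerance = 0.005)
  # beyond the segment end: distance to the nearest vertex
  far <- c(lon = -136.90, lat = 58.86)
  d2 <- distance_to_terminus(far[["lat"]], far[["lon"]], term)
  ref <- geosphere::distGeo(far[c("lon", "lat")], term[2, ]) / 1000
  expect_equal(d2, ref, tolerance = 1e-6)
  expect_true(is.na(distance_to_terminus(NA, NA, term)))
  expect_error(distance_to_terminus(58.9, -137, term[1, , drop = FALSE]),
               class = "icehab_validation_error")
})

test_that("survey aggregation reports sample statistics and permutation-invariant totals", {
  st <- do.call(rbind, lapply(1:3, function(i) {
    m <- make_map(10, 10, brash = 10 * i, iceberg = i)
    scene_stats(m, list(), 0.04, scene_id = paste0("s", i))
  }))
  st$iceberg_pct <- c(1, 2, 3)
  agg <- aggregate_survey(st)
  row <- agg$summary[agg$summary$variable == "iceberg_pct", ]
  expect_equal(row$mean, 2)
  expect_equal(row$sd, 1)
  expect_equal(row$max, 3)
  expect_equal(row$n_images, 3L)
  agg2 <- aggregate_survey(st[c(3, 1, 2), ])
  expect_equal(agg2$total_iceberg_area_m2, agg$total_iceberg_area_m2)
  expect_equal(agg2$total_ice_area_m2, agg$total_ice_area_m2)
  one <- aggregate_survey(st[1, ])
  expect_equal(one$summary$sd, rep(0, nrow(one$summary)))
})

test_that("fjord extrapolation is the linear percentage-times-area product", {
  expect_equal(extrapolate_fjord(2.07, 22), 455400)
  expect_equal(extrapolate_fjord(0, 22), 0)
  expect_equal(extrapolate_fjord(100, 1), 1e6)
  expect_equal(extrapolate_fjord(2 * 1.3, 22), 2 * extrapolate_fjord(1.3, 22))
  expect_equal(extrapolate_fjord(1.3, 22 * 3), 3 * extrapolate_fjord(1.3, 22))
})

test_that("uncertainty combination is quadrature by default", {
  expect_equal(combine_uncertainty(uncertainty_spec(0.26, 0.07)), 0.27)
  expect_equal(combine_uncertainty(uncertainty_spec(0.4, 0)), 0.4)
  expect_equal(combine_uncertainty(uncertainty_spec(0.3, 0.4)), 0.5)
  expect_equal(combine_uncertainty(uncertainty_spec(0.26, 0.07,
                                                    digits = NULL)),
               sqrt(0.26^2 + 0.07^2))
  expect_equal(combine_uncertainty(uncertainty_spec(0.26, 0.07,
                                                    combination = "sum")),
               0.33)
})

test_that("the scale-distortion bound at the survey flying height stays below 7%", {
  expect_lt(scale_distortion_bound(308), 0.07)
  expect_gt(scale_distortion_bound(100), scale_distortion_bound(400))
})

test_that("representativeness resampling is seeded and centered on the grand mean", {
  same <- rep(2.5, 60)
  r <- representativeness_resample(same, n_trials = 50, sample_size = 40,
                                   seed = 3)
  expect_true(all(r$trial_means_pct == 2.5))
  expect_equal(r$sd_trial_means_pct, 0)
  expect_equal(r$se_mean_frac, 0)

  pct <- withr::with_seed(8, rlnorm(200, 0, 0.8))
  r1 <- representativeness_resample(pct, seed = 11)
  r2 <- representativeness_resample(pct, seed = 11)
  expect_identical(r1$trial_means_pct, r2$trial_means_pct)
  se_trial <- sd(pct) / sqrt(40) * sqrt(1 - 40 / 200)
  expect_lt(abs(r1$mean_of_means_pct - mean(pct)), 3 * se_trial)
  expect_equal(r1$se_mean_pct, sd(pct) / sqrt(200))
  expect_error(representativeness_resample(pct[1:10], sample_size = 40),
               class = "icehab_validation_error")
})

test_that("RBF interpolation is exact at data points and reproduces linear fields", {
  pts <- data.frame(x = c(0, 1, 0, 1, 0.4), y = c(0, 0, 1, 1, 0.6),
                    value = 3)
  gs <- list(xlim = c(0, 1), ylim = c(0, 1), nx = 5, ny = 5)
  surf <- interpolate_map(pts, gs)
  expect_true(all(abs(surf$values - 3) < 1e-8))

  pts2 <- withr::with_seed(2, data.frame(x = runif(12), y = runif(12)))
  pts2$value <- 2 + 3 * pts2$x - 5 * pts2$y
  surf2 <- interpolate_map(pts2, gs)
  at_data <- surf2$predict(pts2$x, pts2$y)
  expect_lt(max(abs(at_data - pts2$value) / pmax(abs(pts2$value), 1)), 1e-6)
  gx <- expand.grid(x = surf2$x, y = surf2$y)
  expect_lt(max(abs(as.vector(surf2$values) -
                      (2 + 3 * gx$x - 5 * gx$y))), 1e-6)

  dup <- rbind(pts2, data.frame(x = pts2$x[1], y = pts2$y[1], value = 99))
  expect_error(interpolate_map(dup, gs), class = "icehab_validation_error")
  coll <- data.frame(x = 1:5, y = 2 * (1:5), value = 1:5)
  expect_error(interpolate_map(coll, gs), class = "icehab_validation_error")
})
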