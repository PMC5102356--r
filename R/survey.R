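#' Per-scene statistics
#'
#' Percentages of the classified (non-excluded) scene area in each class,
#' plus per-iceberg summaries. The three percentages sum to 100 exactly;
#' the mean iceberg size is absent (NA) when the scene holds no icebergs.
#'
#' @param class_map Integer class matrix (palette of [ice_classes()]).
#' @param objects List of iceberg objects from [classify_scene()].
#' @param pixel_size_m Pixel size in meters.
#' @param scene_id Scene identifier.
#' @param dist_to_terminus_km Optional distance from the glacier calving
#'   face to the scene center, in km.
#' @return A one-row data frame with columns `scene_id`, `iceberg_pct`,
#'   `brash_pct`, `water_pct`, `n_icebergs`, `iceberg_area_m2`,
#'   `mean_iceberg_size_m2`, `mean_angularity`, `scene_area_m2`,
#'   `dist_to_terminus_km`.
#' @export
scene_stats <- function(class_map, objects, pixel_size_m,
                        scene_id = "scene", dist_to_terminus_km = NA_real_) {
  cls <- ice_classes()
  n_domain <- sum(class_map != cls[["excluded"]])
  if (n_domain == 0L) stop_validation("scene is fully excluded")
  n_ice <- sum(class_map == cls[["iceberg"]])
  n_brash <- sum(class_map == cls[["brash"]])
  n_water <- sum(class_map == cls[["water"]])
  n_obj <- length(objects)
  areas <- vapply(objects, function(o) o$area_m2, numeric(1))
  angs <- vapply(objects, function(o) o$angularity, numeric(1))
  data.frame(
    scene_id = scene_id,
    iceberg_pct = 100 * n_ice / n_domain,
    brash_pct = 100 * n_brash / n_domain,
    water_pct = 100 * n_water / n_domain,
    n_icebergs = n_obj,
    iceberg_area_m2 = n_ice * pixel_size_m^2,
    mean_iceberg_size_m2 = if (n_obj > 0L) mean(areas) else NA_real_,
    mean_angularity = if (n_obj > 0L) mean(angs) else NA_real_,
    scene_area_m2 = n_domain * pixel_size_m^2,
    dist_to_terminus_km = dist_to_terminus_km,
    stringsAsFactors = FALSE)
}

#' Distance from a scene center to the glacier terminus
#'
#' Minimum great-circle distance from the point to the terminus polyline
#' (point-to-segment, not point-to-vertex), in kilometers.
#'
#' @param lat,lon Scene center in decimal degrees (NA gives NA, not an
#'   error: scenes without geolocation are still classifiable).
#' @param terminus Two-column matrix or data frame of polyline vertices with
#'   columns `lon`, `lat` (at least 2 vertices).
#' @return Distance in km (NA if the scene has no coordinates).
#' @export
distance_to_terminus <- function(lat, lon, terminus) {
  tm <- as.matrix(as.data.frame(terminus)[, c("lon", "lat")])
  if (nrow(tm) < 2L)
    stop_validation("terminus polyline needs at least 2 vertices")
  if (is.na(lat) || is.na(lon)) return(NA_real_)
  as.numeric(geosphere::dist2Line(cbind(lon, lat), tm)[1, "distance"]) / 1000
}

#' Aggregate per-scene statistics to survey level
#'
#' Per-variable mean, standard deviation (sample SD, n - 1 denominator; 0 by
#' convention for a single scene), maximum and image count, plus survey
#' totals. Iceberg size and angularity are averaged over scenes where
#' icebergs are present.
#'
#' @param stats Data frame of per-scene rows from [scene_stats()].
#' @return A list of class `survey_stats` with `summary` (one row per
#'   variable), `n_images`, `total_iceberg_area_m2`, `total_ice_area_m2`
#'   and `mean_iceberg_pct`.
#' @export
aggregate_survey <- function(stats) {
  stopifnot(is.data.frame(stats), nrow(stats) >= 1L)
  sd0 <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) 0 else stats::sd(x)
  }
  row <- function(name, x) data.frame(
    variable = name, mean = mean(x, na.rm = TRUE), sd = sd0(x),
    max = if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE),
    n_images = sum(!is.na(x)), stringsAsFactors = FALSE)
  summary <- rbind(
    row("iceberg_pct", stats$iceberg_pct),
    row("brash_pct", stats$brash_pct),
    row("water_pct", stats$water_pct),
    row("iceberg_size_m2", stats$mean_iceberg_size_m2),
    row("iceberg_angularity", stats$mean_angularity),
    row("dist_to_terminus_km", stats$dist_to_terminus_km))
  brash_area <- sum(stats$brash_pct / 100 * stats$scene_area_m2)
  total_iceberg <- sum(stats$iceberg_area_m2)
  structure(list(summary = summary, n_images = nrow(stats),
                 total_iceberg_area_m2 = total_iceberg,
                 total_ice_area_m2 = total_iceberg + brash_area,
                 mean_iceberg_pct = mean(stats$iceberg_pct)),
            class = "survey_stats")
}

#' @export
print.survey_stats <- function(x, ...) {
  cat(sprintf("<survey_stats: %d images, total iceberg area %.0f m2>\n",
              x$n_images, x$total_iceberg_area_m2))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Extrapolate mean iceberg cover to the whole fjord
#'
#' Multiplies the survey-mean iceberg percentage by the fjord water area to
#' estimate total iceberg habitat; linear in both arguments.
#'
#' @param mean_iceberg_pct Mean iceberg percentage over scenes (e.g. 2.07).
#' @param fjord_area_km2 Fjord water area in km2 (e.g. 22).
#' @return Iceberg area in m2.
#' @export
extrapolate_fjord <- function(mean_iceberg_pct, fjord_area_km2) {
  stopifnot(mean_iceberg_pct >= 0, fjord_area_km2 > 0)
  mean_iceberg_pct / 100 * fjord_area_km2 * 1e6
}

#' Uncertainty specification for the iceberg-area estimate
#'
#' Two uncertainty sources: classification error (whole icebergs
#' misclassified as brash ice; default 0.26, the underestimate observed when
#' comparing automated to manually corrected icebergs) and scale distortion
#' at frame edges (default 0.07, an upper bound from the flying height).
#' The default combination is in quadrature: the arithmetic sum would
#' overstate the total for independent error sources.
#'
#' @param classification_frac Classification uncertainty as a fraction.
#' @param distortion_frac Scale-distortion uncertainty as a fraction.
#' @param combination `"quadrature"` (default) or `"sum"`.
#' @param digits Decimal places on the combined fraction (default 2, i.e.
#'   whole percent); `NULL` leaves it unrounded.
#' @return An object of class `uncertainty_spec`.
#' @export
uncertainty_spec <- function(classification_frac = 0.26,
                             distortion_frac = 0.07,
                             combination = c("quadrature", "sum"),
                             digits = 2) {
  stopifnot(classification_frac >= 0, distortion_frac >= 0)
  structure(list(classification_frac = classification_frac,
                 distortion_frac = distortion_frac,
                 combination = match.arg(combination), digits = digits),
            class = "uncertainty_spec")
}

#' Combine uncertainty sources
#'
#' @param spec An [uncertainty_spec()].
#' @return Combined uncertainty as a fraction (e.g. 0.27 for 26% and 7%
#'   combined in quadrature at the default rounding).
#' @export
combine_uncertainty <- function(spec = uncertainty_spec()) {
  stopifnot(inherits(spec, "uncertainty_spec"))
  u <- switch(spec$combination,
              quadrature = sqrt(spec$classification_frac^2 +
                                spec$distortion_frac^2),
              sum = spec$classification_frac + spec$distortion_frac)
  if (!is.null(spec$digits)) u <- round(u, spec$digits)
  u
}

#' Scale-distortion bound from the flying height
#'
#' Flat-water pinhole-model bound on the relative scale distortion at the
#' frame corner: the photographic scale at off-nadir angle `theta` departs
#' from the nadir scale by a factor `1 / cos(theta)^2` (one cosine for the
#' slant range, one for the obliquity), so the fractional bound is
#' `1 / cos(theta_max)^2 - 1`. At a 308 m flying height over an
#' 80.7 x 121.8 m frame this is below 7%.
#'
#' @param altitude_m Flying height in meters (e.g. 308).
#' @param half_diag_m Ground distance from frame center to corner
#'   (default from an 80.7 x 121.8 m frame).
#' @return Fractional scale-distortion bound.
#' @export
scale_distortion_bound <- function(altitude_m,
                                   half_diag_m = sqrt(80.7^2 + 121.8^2) / 2) {
  stopifnot(altitude_m > 0, half_diag_m > 0)
  theta <- atan(half_diag_m / altitude_m)
  1 / cos(theta)^2 - 1
}

#' Resampling check of survey representativeness
#'
#' Draws seeded trials of scenes without replacement and records the mean
#' iceberg percentage of each trial; a trial-mean distribution centered on
#' the full-survey mean indicates the sampled frames represent the fjord.
#' Also returns the analytic standard error of the full-survey mean
#' fraction, `sd(fraction) / sqrt(n)`.
#'
#' @param stats Data frame of per-scene rows (needs `iceberg_pct`), or a
#'   numeric vector of percentages.
#' @param n_trials Number of trials (default 100).
#' @param sample_size Scenes per trial (default 40).
#' @param seed Integer seed.
#' @return A list with `trial_means_pct`, `mean_of_means_pct`,
#'   `grand_mean_pct`, `sd_trial_means_pct`, `se_mean_frac` and
#'   `se_mean_pct`.
#' @export
representativeness_resample <- function(stats, n_trials = 100L,
                                        sample_size = 40L, seed = 1L) {
  pct <- if (is.data.frame(stats)) stats$iceberg_pct else as.numeric(stats)
  n <- length(pct)
  if (sample_size > n)
    stop_validation("sample_size exceeds the number of scenes")
  stopifnot(n_trials >= 1L, sample_size >= 1L)
  tm <- with_local_seed(seed, vapply(
    seq_len(n_trials), function(i) mean(sample(pct, sample_size)), numeric(1)))
  list(trial_means_pct = tm,
       mean_of_means_pct = mean(tm),
       grand_mean_pct = mean(pct),
       sd_trial_means_pct = if (n_trials > 1L) stats::sd(tm) else 0,
       se_mean_frac = stats::sd(pct / 100) / sqrt(n),
       se_mean_pct = stats::sd(pct) / sqrt(n))
}

#' Exact radial-basis-function interpolation of scene values
#'
#' Grids scattered per-scene values (e.g. percent iceberg cover at scene
#' centers) to a continuous surface with an exact interpolator: the surface
#' passes through every measured point and can predict values above the
#' maximum and below the minimum measurement. The default kernel is the
#' thin-plate spline `U(r) = r^2 log r` with an affine polynomial part,
#' which reproduces linear fields exactly.
#'
#' @param points Data frame with columns `x`, `y`, `value`.
#' @param grid_spec List with `xlim`, `ylim` (length-2) and `nx`, `ny`.
#' @param kernel `"thin_plate"` (default) or `"linear"` (`U(r) = r`).
#' @return A list with `x`, `y` (grid coordinates), `values`
#'   (`nx` x `ny` matrix, `values[i, j]` at `(x[i], y[j])`), and `predict`,
#'   a function of `(x, y)` vectors evaluating the surface anywhere.
#' @export
interpolate_map <- function(points, grid_spec, kernel = "thin_plate") {
  stopifnot(all(c("x", "y", "value") %in% names(points)))
  pts <- unique(points[, c("x", "y", "value")])
  key <- paste(pts$x, pts$y)
  if (anyDuplicated(key))
    stop_validation("duplicate points with conflicting values")
  if (nrow(pts) < 3L)
    stop_validation("interpolation needs at least 3 points")
  x <- pts$x; y <- pts$y; v <- pts$value
  if (qr(cbind(1, x, y))$rank < 3L)
    stop_validation("interpolation points are collinear")
  U <- function(r) {
    if (kernel == "linear") return(r)
    w <- r * r * log(r)
    w[r == 0] <- 0
    w
  }
  n <- length(x)
  K <- U(sqrt(outer(x, x, "-")^2 + outer(y, y, "-")^2))
  P <- cbind(1, x, y)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  coef <- solve(A, c(v, 0, 0, 0))
  w <- coef[seq_len(n)]
  a <- coef[n + 1:3]
  predict_fun <- function(px, py) {
    G <- U(sqrt(outer(px, x, "-")^2 + outer(py, y, "-")^2))
    as.numeric(G %*% w + a[1] + a[2] * px + a[3] * py)
  }
  gx <- seq(grid_spec$xlim[1], grid_spec$xlim[2], length.out = grid_spec$nx)
  gy <- seq(grid_spec$ylim[1], grid_spec$ylim[2], length.out = grid_spec$ny)
  grid <- expand.grid(x = gx, y = gy)
  z <- matrix(predict_fun(grid$x, grid$y), nrow = grid_spec$nx)
  list(x = gx, y = gy, values = z, predict = predict_fun)
}
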