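#' Label-raster palette
#'
#' Class label rasters are written as 8-bit grayscale PNG holding the raw
#' integer codes of [ice_classes()] (0 excluded, 1 water, 2 brash,
#' 3 iceberg), so a write/read round trip reproduces the class grid exactly.
#' Georeferencing (pixel size, scene center) travels in a JSON sidecar next
#' to the raster.
#'
#' @param class_map Integer class matrix.
#' @param path Output PNG path.
#' @param pixel_size_m Optional pixel size recorded in the sidecar.
#' @param lat,lon Optional scene center recorded in the sidecar.
#' @return The raster path, invisibly.
#' @export
write_label_raster <- function(class_map, path, pixel_size_m = NULL,
                               lat = NA_real_, lon = NA_real_) {
  if (any(class_map < 0L | class_map > 255L))
    stop_validation("class codes must fit one byte")
  png::writePNG(class_map / 255, path)
  if (is.null(pixel_size_m))
    pixel_size_m <- attr(class_map, "pixel_size_m")
  if (!is.null(pixel_size_m) || !is.na(lat)) {
    side <- sub("\\.png$", ".json", path)
    jsonlite::write_json(
      list(pixel_size_m = pixel_size_m, center_lat = lat, center_lon = lon,
           palette = as.list(ice_classes())),
      side, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a label raster written by [write_label_raster()]
#'
#' @param path PNG path.
#' @return Integer class matrix; the sidecar pixel size, when present, is
#'   attached as attribute `pixel_size_m`.
#' @export
read_label_raster <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("label raster not found: %s", path))
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  m <- matrix(as.integer(round(v * 255)), nrow(v), ncol(v))
  side <- sub("\\.png$", ".json", path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (!is.null(meta$pixel_size_m))
      attr(m, "pixel_size_m") <- as.numeric(meta$pixel_size_m)
  }
  m
}

# Boundary rings of a mask via half-level contours on a zero-padded grid;
# returns a list of two-column (row, col) matrices in fractional pixels.
mask_rings <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  z <- matrix(0, nr + 2L, nc + 2L)
  z[2:(nr + 1L), 2:(nc + 1L)] <- mask * 1
  cl <- grDevices::contourLines(x = 0:(nr + 1L), y = 0:(nc + 1L), z = z,
                                levels = 0.5)
  lapply(cl, function(cc) cbind(row = cc$x, col = cc$y))
}

#' Write iceberg outlines as GeoJSON
#'
#' Each iceberg becomes a polygon feature with `object_id`, `area_m2`,
#' `perimeter_m` and `angularity` properties. When the scene is
#' georeferenced, ring coordinates are longitude/latitude computed from the
#' scene center with a local meters-per-degree approximation; otherwise they
#' are local meters (x east, y north, origin at the bottom-left pixel
#' corner).
#'
#' @param objects List of iceberg objects from [classify_scene()].
#' @param shape Integer vector `c(nrow, ncol)` of the scene grid.
#' @param pixel_size_m Pixel size in meters.
#' @param path Output GeoJSON path.
#' @param lat,lon Optional scene center for georeferencing.
#' @return The path, invisibly.
#' @export
write_iceberg_geojson <- function(objects, shape, pixel_size_m, path,
                                  lat = NA_real_, lon = NA_real_) {
  nr <- shape[1]; nc <- shape[2]
  geo <- !is.na(lat) && !is.na(lon)
  to_coords <- function(ring) {
    x_m <- ring[, "col"] * pixel_size_m
    y_m <- (nr - ring[, "row"]) * pixel_size_m
    if (geo) {
      m_per_deg_lat <- 111320
      m_per_deg_lon <- 111320 * cos(lat * pi / 180)
      cx <- nc / 2 * pixel_size_m
      cy <- nr / 2 * pixel_size_m
      cbind(lon + (x_m - cx) / m_per_deg_lon, lat + (y_m - cy) / m_per_deg_lat)
    } else {
      cbind(x_m, y_m)
    }
  }
  feats <- lapply(objects, function(o) {
    mask <- matrix(FALSE, nr, nc)
    mask[o$pixels] <- TRUE
    rings <- mask_rings(mask)
    coords <- lapply(rings, function(rg) {
      cc <- to_coords(rg)
      if (any(cc[1, ] != cc[nrow(cc), ])) cc <- rbind(cc, cc[1, ])
      lapply(seq_len(nrow(cc)), function(i) c(cc[i, 1], cc[i, 2]))
    })
    list(type = "Feature",
         properties = list(object_id = o$object_id, area_m2 = o$area_m2,
                           perimeter_m = o$perimeter_m,
                           angularity = o$angularity),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' Read a GeoJSON geometry file
#'
#' Minimal reader for the package's vector inputs: a terminus polyline
#' (LineString) or fjord boundary (Polygon). Returns the coordinates of the
#' first feature (or bare geometry) as a two-column `lon`/`lat` matrix.
#'
#' @param path GeoJSON path.
#' @return Matrix with columns `lon`, `lat`.
#' @export
read_geojson_coords <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("GeoJSON not found: %s", path))
  gj <- jsonlite::read_json(path)
  geom <- if (!is.null(gj$features)) gj$features[[1]]$geometry else
    if (!is.null(gj$geometry)) gj$geometry else gj
  coords <- geom$coordinates
  if (identical(geom$type, "Polygon")) coords <- coords[[1]]
  m <- do.call(rbind, lapply(coords, function(p)
    c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  colnames(m) <- c("lon", "lat")
  m
}

#' Write all per-scene outputs
#'
#' Writes (a) the class label raster as PNG with the documented palette and
#' a JSON georeferencing sidecar, (b) iceberg polygons as GeoJSON with
#' area and angularity properties, and (c) the one-row scene statistics CSV.
#'
#' @param class_map Integer class matrix from [classify_scene()].
#' @param objects Iceberg object list from [classify_scene()].
#' @param stats One-row data frame from [scene_stats()].
#' @param out_dir Output directory (created if needed).
#' @param scene_id Scene identifier used in file names.
#' @param pixel_size_m Pixel size in meters.
#' @param lat,lon Optional scene center.
#' @return Named character vector of the three paths.
#' @export
write_outputs <- function(class_map, objects, stats, out_dir,
                          scene_id = stats$scene_id[1],
                          pixel_size_m = attr(class_map, "pixel_size_m"),
                          lat = NA_real_, lon = NA_real_) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop_io(sprintf("cannot write to output directory: %s", out_dir))
  raster <- file.path(out_dir, paste0(scene_id, "_classes.png"))
  vect <- file.path(out_dir, paste0(scene_id, "_icebergs.geojson"))
  tab <- file.path(out_dir, paste0(scene_id, "_stats.csv"))
  write_label_raster(class_map, raster, pixel_size_m, lat, lon)
  write_iceberg_geojson(objects, dim(class_map), pixel_size_m, vect, lat, lon)
  utils::write.csv(stats, tab, row.names = FALSE)
  c(raster = raster, vector = vect, stats = tab)
}

#' Write a scene image as PNG
#'
#' @param scene A [scene_image()].
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
write_scene_png <- function(scene, path) {
  png::writePNG(scene$pixels, path)
  invisible(path)
}
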