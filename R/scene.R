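#' Construct a scene image
#'
#' A scene is one non-overlapping aerial sampling frame: an RGB pixel array in
#' `[0, 1]` with a known ground pixel size in meters and optional
#' georeferencing. The raster convention throughout the package is row-major
#' with the origin at the top-left; areas are always reported in square meters
#' using `pixel_size_m^2`.
#'
#' @param pixels Numeric array `height x width x 3` with values in `[0, 1]`.
#' @param pixel_size_m Ground size of one (square) pixel, in meters.
#' @param scene_id Character identifier.
#' @param lat,lon Optional scene-center coordinates in decimal degrees.
#' @param altitude_m Optional flying height in meters.
#' @param exclusion_mask Optional logical matrix of the same height/width;
#'   `TRUE` pixels (land, glacier face) are excluded from classification.
#' @return An object of class `scene_image`.
#' @export
scene_image <- function(pixels, pixel_size_m, scene_id = "scene",
                        lat = NA_real_, lon = NA_real_,
                        altitude_m = NA_real_, exclusion_mask = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_validation("pixels must be a height x width x 3 array")
  if (any(dim(pixels)[1:2] < 1L))
    stop_validation("scene must have positive width and height")
  if (!is.numeric(pixel_size_m) || length(pixel_size_m) != 1L ||
      is.na(pixel_size_m) || pixel_size_m <= 0)
    stop_validation("pixel_size_m must be a single positive number")
  rng <- range(pixels)
  if (rng[1] < -1e-8 || rng[2] > 1 + 1e-8)
    stop_validation("channel values must lie in [0, 1]")
  pixels[] <- clip01(pixels)
  if (!is.null(exclusion_mask)) {
    if (!is.logical(exclusion_mask) ||
        !identical(dim(exclusion_mask), dim(pixels)[1:2]))
      stop_validation("exclusion_mask must be a logical matrix matching pixels")
  }
  structure(
    list(scene_id = as.character(scene_id), pixels = pixels,
         pixel_size_m = pixel_size_m, lat = lat, lon = lon,
         altitude_m = altitude_m, exclusion_mask = exclusion_mask),
    class = "scene_image")
}

#' @export
print.scene_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<scene_image '%s': %d x %d px @ %.4g m/px (%.1f x %.1f m)%s>\n",
              x$scene_id, d[1], d[2], x$pixel_size_m,
              d[1] * x$pixel_size_m, d[2] * x$pixel_size_m,
              if (is.na(x$lat)) "" else sprintf(", %.5f N %.5f E", x$lat, x$lon)))
  invisible(x)
}

#' Read a scene metadata table
#'
#' The metadata table is a plain CSV with one row per scene: `scene_id` plus
#' any of `lat`, `lon`, `altitude_m`, `pixel_size_m`, `footprint_width_m`
#' (ground distance spanned by the image columns, from which the pixel size is
#' derived when `pixel_size_m` is absent).
#'
#' @param path Path to the CSV file.
#' @return A data frame with one row per scene.
#' @export
read_scene_metadata <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("metadata file not found: %s", path))
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"scene_id" %in% names(md))
    stop_validation("metadata must contain a scene_id column")
  md
}

#' Load a scene image with its metadata
#'
#' Reads a JPEG/PNG/TIFF aerial frame, rescales channels to `[0, 1]`, and
#' attaches the metadata row. The pixel size is taken from
#' `metadata_row$pixel_size_m`, or derived as
#' `footprint_width_m / image width` when only the footprint is known.
#' Missing geolocation is tolerated: the scene is still classifiable.
#'
#' @param image_path Path to an RGB image file.
#' @param metadata_row A named list or one-row data frame (see
#'   [read_scene_metadata()]); may be `NULL` if `pixel_size_m` is given.
#' @param pixel_size_m Pixel size override in meters.
#' @return A [scene_image()].
#' @export
load_scene <- function(image_path, metadata_row = NULL, pixel_size_m = NULL) {
  if (!file.exists(image_path))
    stop_io(sprintf("cannot read scene image: %s", image_path))
  img <- tryCatch(EBImage::readImage(image_path),
                  error = function(e) stop_io(sprintf(
                    "cannot decode scene image %s: %s", image_path,
                    conditionMessage(e))))
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 2L)
    stop_validation("scene image must be 3-channel RGB")
  if (dim(d)[3] > 3L) d <- d[, , 1:3, drop = FALSE]  # drop alpha
  # EBImage stores (x, y, channel); convert to (row, col, channel)
  px <- aperm(d, c(2L, 1L, 3L))
  md <- if (is.data.frame(metadata_row)) as.list(metadata_row[1L, ]) else
    as.list(metadata_row)
  getf <- function(nm) {
    v <- md[[nm]]
    if (is.null(v) || length(v) == 0L || is.na(v)) NA_real_ else as.numeric(v)
  }
  ps <- if (!is.null(pixel_size_m)) pixel_size_m else getf("pixel_size_m")
  if (is.na(ps)) {
    fw <- getf("footprint_width_m")
    if (!is.na(fw)) ps <- fw / dim(px)[2]
  }
  if (is.na(ps))
    stop_validation("pixel_size_m missing and not derivable from metadata")
  if (ps <= 0) stop_validation("pixel size must be positive")
  sid <- md[["scene_id"]]
  if (is.null(sid) || is.na(sid))
    sid <- sub("\\.[^.]+$", "", basename(image_path))
  scene_image(px, pixel_size_m = ps, scene_id = sid,
              lat = getf("lat"), lon = getf("lon"),
              altitude_m = getf("altitude_m"))
}

#' Resample a scene to a target pixel size
#'
#' Bilinear resampling to a standard ground resolution (0.04 m by default, the
#' survey standard). A scene already at the target resolution is returned
#' unchanged. The exclusion mask, when present, is resampled by nearest
#' neighbor.
#'
#' @param scene A [scene_image()].
#' @param target_pixel_size_m Target pixel size in meters.
#' @return A [scene_image()] at the target resolution.
#' @export
standardize_resolution <- function(scene, target_pixel_size_m = 0.04) {
  stopifnot(inherits(scene, "scene_image"))
  if (!is.numeric(target_pixel_size_m) || target_pixel_size_m <= 0)
    stop_validation("target pixel size must be positive")
  ps <- scene$pixel_size_m
  if (isTRUE(all.equal(ps, target_pixel_size_m))) return(scene)
  d <- dim(scene$pixels)
  new_nr <- max(1L, floor(d[1] * ps / target_pixel_size_m))
  new_nc <- max(1L, floor(d[2] * ps / target_pixel_size_m))
  # EBImage::resize is symmetric in the two spatial axes, so the
  # (row, col, channel) array can be passed directly
  out <- EBImage::imageData(EBImage::resize(
    EBImage::Image(scene$pixels, colormode = "Color"),
    w = new_nr, h = new_nc, filter = "bilinear"))
  out <- clip01(out)
  mask <- scene$exclusion_mask
  if (!is.null(mask)) {
    m <- EBImage::imageData(EBImage::resize(
      EBImage::Image(mask * 1), w = new_nr, h = new_nc, filter = "none"))
    mask <- m > 0.5
  }
  scene_image(out, pixel_size_m = target_pixel_size_m,
              scene_id = scene$scene_id, lat = scene$lat, lon = scene$lon,
              altitude_m = scene$altitude_m, exclusion_mask = mask)
}

#' Enhancement parameters
#'
#' Defined, auditable counterparts of the photo-editor settings used to
#' prepare survey frames: a linear contrast expansion about mid-gray, a
#' vibrance-style saturation boost weighted toward low-saturation pixels, and
#' an unsharp mask. All gains of zero give the identity.
#'
#' @param contrast_gain Fractional contrast expansion about 0.5 (default 0.2,
#'   i.e. gain 1.2, the counterpart of a "+20 contrast" slider).
#' @param vibrance_gain Fractional saturation boost, applied with weight
#'   `(1 - saturation)` so saturated pixels are left alone (default 0.2).
#' @param sharpen_amount Unsharp-mask amount (default 0.4, counterpart of
#'   "amount 40").
#' @param sharpen_sigma Gaussian radius of the unsharp mask in pixels
#'   (default 1.0).
#' @return An object of class `enhance_params`.
#' @export
enhance_params <- function(contrast_gain = 0.2, vibrance_gain = 0.2,
                           sharpen_amount = 0.4, sharpen_sigma = 1.0) {
  stopifnot(contrast_gain >= 0, vibrance_gain >= 0, sharpen_amount >= 0,
            sharpen_sigma > 0)
  structure(list(contrast_gain = contrast_gain, vibrance_gain = vibrance_gain,
                 sharpen_amount = sharpen_amount,
                 sharpen_sigma = sharpen_sigma),
            class = "enhance_params")
}

#' Enhance a scene
#'
#' Applies, in order: (1) linear contrast expansion about mid-gray; (2)
#' saturation boost of low-saturation pixels; (3) unsharp masking with a
#' Gaussian blur. The output is clipped to `[0, 1]`. A constant mid-gray
#' image is a fixed point of contrast and sharpening.
#'
#' @param scene A [scene_image()].
#' @param params An [enhance_params()] object.
#' @return The enhanced [scene_image()].
#' @export
enhance <- function(scene, params = enhance_params()) {
  stopifnot(inherits(scene, "scene_image"), inherits(params, "enhance_params"))
  px <- scene$pixels
  if (params$contrast_gain > 0)
    px <- clip01(0.5 + (1 + params$contrast_gain) * (px - 0.5))
  if (params$vibrance_gain > 0)
    px <- boost_vibrance(px, params$vibrance_gain)
  if (params$sharpen_amount > 0) {
    for (ch in 1:3) {
      v <- px[, , ch]
      blur <- EBImage::imageData(EBImage::gblur(
        EBImage::Image(v), sigma = params$sharpen_sigma))
      px[, , ch] <- v + params$sharpen_amount * (v - blur)
    }
    px <- clip01(px)
  }
  scene_image(px, pixel_size_m = scene$pixel_size_m,
              scene_id = scene$scene_id, lat = scene$lat, lon = scene$lon,
              altitude_m = scene$altitude_m,
              exclusion_mask = scene$exclusion_mask)
}

# Vibrance: scale per-pixel HSV saturation s by (1 + gain * (1 - s)),
# preserving hue and value (chroma rescaling).
boost_vibrance <- function(px, gain) {
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  v <- pmax(r, g, b)
  m <- pmin(r, g, b)
  s <- ifelse(v > 0, 1 - m / v, 0)
  s2 <- clip01(s * (1 + gain * (1 - s)))
  ratio <- ifelse(s > 0, s2 / s, 1)
  out <- px
  out[, , 1] <- v - (v - r) * ratio
  out[, , 2] <- v - (v - g) * ratio
  out[, , 3] <- v - (v - b) * ratio
  clip01(out)
}

#' Derive the intensity channel of a scene
#'
#' The intensity component of the RGB-to-IHS transform: the per-pixel mean of
#' the three channels. The single intensity channel is what the rule set uses
#' to delineate light (ice) and dark (water) features.
#'
#' @param scene A [scene_image()].
#' @return An object of class `intensity_image` with fields `values` (matrix
#'   in `[0, 1]`) and `pixel_size_m`.
#' @export
rgb_to_intensity <- function(scene) {
  stopifnot(inherits(scene, "scene_image"))
  vals <- (scene$pixels[, , 1] + scene$pixels[, , 2] + scene$pixels[, , 3]) / 3
  structure(list(values = vals, pixel_size_m = scene$pixel_size_m),
            class = "intensity_image")
}
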