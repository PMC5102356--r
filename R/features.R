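#' Grey-level co-occurrence matrix specification
#'
#' @param n_levels Number of quantization levels (default 32). Quantization
#'   is global per scene (over the supplied intensity range), not per object,
#'   so that the texture threshold is comparable across objects.
#' @param offsets List of integer pixel displacement `c(drow, dcol)` vectors;
#'   defaults to the four standard directions (0,1), (1,0), (1,1), (1,-1).
#' @param symmetric Count each pair in both directions (default `TRUE`).
#' @return An object of class `glcm_spec`.
#' @export
glcm_spec <- function(n_levels = 32L,
                      offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L),
                                     c(1L, -1L)),
                      symmetric = TRUE) {
  stopifnot(n_levels >= 2L, length(offsets) >= 1L)
  for (o in offsets)
    if (length(o) != 2L || all(o == 0L))
      stop_validation("offsets must be non-zero length-2 displacement vectors")
  structure(list(n_levels = as.integer(n_levels), offsets = offsets,
                 symmetric = isTRUE(symmetric)),
            class = "glcm_spec")
}

# Quantize intensities into 0..(n_levels-1) over a fixed range.
quantize_levels <- function(vals, n_levels, rng) {
  if (diff(rng) <= 0) return(array(0L, dim = dim(vals)))
  q <- floor((vals - rng[1]) / diff(rng) * n_levels)
  q[q < 0L] <- 0L
  q[q >= n_levels] <- n_levels - 1L
  storage.mode(q) <- "integer"
  q
}

# GLCM homogeneity of every positive label at once. Pairs must lie entirely
# inside one segment (no bleed across borders). Returns a numeric vector
# indexed 1..n_labels; labels with no valid pair get NA.
segment_homogeneity <- function(vals, labels, spec = glcm_spec(),
                                rng = range(vals)) {
  n_lab <- max(labels, 0L)
  if (n_lab == 0L) return(numeric(0))
  q <- quantize_levels(vals, spec$n_levels, rng)
  nr <- nrow(vals); nc <- ncol(vals)
  wsum <- numeric(n_lab)
  npair <- numeric(n_lab)
  for (off in spec$offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    if (length(r1) < 1L || length(c1) < 1L) next
    la <- labels[r1, c1, drop = FALSE]
    lb <- labels[r1 + dr, c1 + dc, drop = FALSE]
    ok <- la > 0L & la == lb
    if (!any(ok)) next
    dq <- q[r1, c1, drop = FALSE][ok] - q[r1 + dr, c1 + dc, drop = FALSE][ok]
    w <- 1 / (1 + dq * dq)
    lab_ok <- la[ok]
    agg <- rowsum(cbind(w, 1), lab_ok)
    ids <- as.integer(rownames(agg))
    wsum[ids] <- wsum[ids] + agg[, 1]
    npair[ids] <- npair[ids] + agg[, 2]
  }
  out <- ifelse(npair > 0, wsum / npair, NA_real_)
  out
}

#' GLCM homogeneity of one object
#'
#' Intensities are quantized to `n_levels` over the scene's intensity range;
#' co-occurring pairs fully inside the object mask are accumulated over all
#' offsets (and their opposites when symmetric) and normalized to
#' probabilities `P`. Returns `sum_ij P(i,j) / (1 + (i - j)^2)`, a value in
#' `(0, 1]`: 1 for perfectly smooth objects, small for strongly textured
#' ones. (Counting pairs in both directions leaves the statistic unchanged,
#' since the pair weight is symmetric.)
#'
#' @param intensity An `intensity_image` or numeric matrix (the full scene,
#'   which fixes the quantization range).
#' @param object_mask Logical matrix selecting the object.
#' @param spec A [glcm_spec()].
#' @param range Quantization range (default: range of `intensity`).
#' @return Homogeneity value in `(0, 1]`.
#' @export
glcm_homogeneity <- function(intensity, object_mask, spec = glcm_spec(),
                             range = NULL) {
  vals <- if (inherits(intensity, "intensity_image")) intensity$values else
    intensity
  stopifnot(identical(dim(object_mask), dim(vals)))
  if (!any(object_mask)) stop_degenerate("empty object mask")
  rng <- if (is.null(range)) base::range(vals) else range
  labels <- matrix(0L, nrow(vals), ncol(vals))
  labels[object_mask] <- 1L
  h <- segment_homogeneity(vals, labels, spec, rng)
  if (length(h) < 1L || is.na(h[1]))
    stop_degenerate("object has no valid co-occurring pixel pair")
  h[1]
}

#' Object area in square meters
#'
#' @param object_mask Logical matrix.
#' @param pixel_size_m Pixel size in meters.
#' @return Pixel count times `pixel_size_m^2`. At the 0.04 m survey standard,
#'   1000 pixels correspond to 1.6 m2, the minimum iceberg size.
#' @export
object_area <- function(object_mask, pixel_size_m) {
  n <- sum(object_mask)
  if (n == 0L) stop_validation("empty object mask")
  n * pixel_size_m^2
}

#' Object crack perimeter in meters
#'
#' The perimeter is measured along the pixel lattice ("crack" boundary): the
#' number of pixel edges adjacent to a non-object pixel or the image border,
#' times the pixel size. A single pixel has perimeter `4 * pixel_size_m`; a
#' filled w x h rectangle has `2 * (w + h) * pixel_size_m`. This convention
#' makes the angularity of compact shapes at least 1 and increasing with
#' boundary raggedness.
#'
#' @inheritParams object_area
#' @return Perimeter in meters.
#' @export
object_perimeter <- function(object_mask, pixel_size_m) {
  crack_edges(object_mask) * pixel_size_m
}

# Exposed pixel-edge count of a mask.
crack_edges <- function(mask) {
  n <- sum(mask)
  if (n == 0L) stop_validation("empty object mask")
  nr <- nrow(mask); nc <- ncol(mask)
  horiz <- if (nc > 1L) sum(mask[, -nc] & mask[, -1L]) else 0L
  vert <- if (nr > 1L) sum(mask[-nr, ] & mask[-1L, ]) else 0L
  4L * n - 2L * (horiz + vert)
}

#' Minimum-perimeter enclosing rotated rectangle
#'
#' Smallest-perimeter rectangle (any orientation) enclosing all object pixel
#' centers, computed by rotating calipers over the convex hull; the optimal
#' rectangle has a side collinear with a hull edge. Side lengths are padded
#' by one pixel so the rectangle covers pixel extents, which also keeps
#' degenerate single-pixel or collinear objects well-defined.
#'
#' @param object_mask Logical matrix.
#' @return A list with `width_px`, `height_px` (padded side lengths),
#'   `angle_rad`, `center` (row, col) and `perimeter_px`.
#' @export
min_enclosing_rect <- function(object_mask) {
  pts <- which(object_mask, arr.ind = TRUE)
  if (nrow(pts) == 0L) stop_validation("empty object mask")
  x <- pts[, 2]; y <- pts[, 1]
  best <- NULL
  eval_angle <- function(theta) {
    ct <- cos(theta); st <- sin(theta)
    u <- x * ct + y * st
    v <- -x * st + y * ct
    w <- diff(range(u)) + 1
    h <- diff(range(v)) + 1
    list(width_px = w, height_px = h, angle_rad = theta,
         center = c(row = mean(range(y)), col = mean(range(x))),
         perimeter_px = 2 * (w + h))
  }
  hull <- grDevices::chull(x, y)
  angles <- if (length(hull) < 2L) 0 else {
    hx <- x[hull]; hy <- y[hull]
    nxt <- c(seq_along(hull)[-1L], 1L)
    a <- atan2(hy[nxt] - hy, hx[nxt] - hx)
    unique(a[is.finite(a)])
  }
  if (length(angles) == 0L) angles <- 0
  for (th in angles) {
    cand <- eval_angle(th)
    if (is.null(best) || cand$perimeter_px < best$perimeter_px) best <- cand
  }
  best
}

#' Object angularity
#'
#' Ratio of the object's crack perimeter to the perimeter of the smallest
#' (minimum-perimeter, rotated) rectangle that can enclose the object. A
#' filled axis-aligned rectangle has angularity exactly 1; ragged outlines
#' give larger values.
#'
#' @inheritParams object_area
#' @param axis_aligned Use the axis-aligned bounding rectangle instead of the
#'   rotated one (default `FALSE`).
#' @return Dimensionless angularity (> 0).
#' @export
angularity <- function(object_mask, pixel_size_m = 1, axis_aligned = FALSE) {
  per <- crack_edges(object_mask)
  rect_per <- if (axis_aligned) {
    pts <- which(object_mask, arr.ind = TRUE)
    2 * ((diff(range(pts[, 2])) + 1) + (diff(range(pts[, 1])) + 1))
  } else {
    min_enclosing_rect(object_mask)$perimeter_px
  }
  per / rect_per
}

#' Write a per-object feature table
#'
#' @param objects List of iceberg objects (see [classify_scene()]).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_object_table <- function(objects, path) {
  df <- if (length(objects) == 0L) {
    data.frame(object_id = integer(), n_pixels = integer(),
               area_m2 = numeric(), perimeter_m = numeric(),
               angularity = numeric())
  } else {
    do.call(rbind, lapply(objects, function(o)
      data.frame(object_id = o$object_id, n_pixels = o$n_pixels,
                 area_m2 = o$area_m2, perimeter_m = o$perimeter_m,
                 angularity = o$angularity)))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
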