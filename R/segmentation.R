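#' Threshold search specification for contrast-split segmentation
#'
#' The split threshold is chosen from a candidate grid of evenly spaced
#' intensities between two percentiles of the domain (bounded cost,
#' insensitive to outlier pixels) by maximizing a contrast objective between
#' the resulting bright and dark pixel sets.
#'
#' @param n_candidates Number of evenly spaced candidate thresholds
#'   (default 25).
#' @param lower_pct,upper_pct Percentile bounds of the candidate grid
#'   (defaults 0.01 and 0.99).
#' @param objective `"between_class_variance"` (Otsu's criterion
#'   `w_dark * w_bright * (mean_bright - mean_dark)^2`, the default),
#'   `"mean_diff"` (unweighted difference of class means) or `"mean_ratio"`
#'   (ratio of class means). The weighted default is robust on skewed
#'   compositions: an unweighted mean difference is maximized by splitting
#'   off a handful of extreme pixels whenever one class is rare.
#' @param min_contrast Minimum accepted contrast, measured as
#'   `mean(bright) - mean(dark)` at the chosen threshold (default 0.25
#'   intensity units, about half the typical water-ice reflectance contrast
#'   and above the spurious contrast of plain water speckle). A split whose
#'   classes differ by less is rejected as degenerate. Set to 0 to accept
#'   any maximizer.
#' @return An object of class `threshold_search_spec`.
#' @export
threshold_search_spec <- function(n_candidates = 25L, lower_pct = 0.01,
                                  upper_pct = 0.99,
                                  objective = c("between_class_variance",
                                                "mean_diff", "mean_ratio"),
                                  min_contrast = 0.25) {
  stopifnot(n_candidates >= 2L, lower_pct >= 0, upper_pct <= 1,
            lower_pct < upper_pct, min_contrast >= 0)
  structure(list(n_candidates = as.integer(n_candidates),
                 lower_pct = lower_pct, upper_pct = upper_pct,
                 objective = match.arg(objective),
                 min_contrast = min_contrast),
            class = "threshold_search_spec")
}

#' Contrast-split segmentation
#'
#' Splits an intensity image (or the part of it inside `domain`) into bright
#' and dark pixel sets at the threshold that maximizes the contrast objective.
#' Ties are broken toward the lowest threshold. Every bright pixel has
#' intensity `>= threshold` and every dark pixel `< threshold`; the two masks
#' partition the domain.
#'
#' @param intensity An `intensity_image` (see [rgb_to_intensity()]) or a
#'   numeric matrix.
#' @param domain Optional logical matrix restricting the split.
#' @param search A [threshold_search_spec()].
#' @return A list of class `contrast_split_result` with `threshold`,
#'   `bright_mask`, `dark_mask`, `objective_value` (value of the configured
#'   objective at the threshold) and `mean_contrast` (bright minus dark
#'   class mean, the quantity checked against `min_contrast`).
#' @export
contrast_split <- function(intensity, domain = NULL,
                           search = threshold_search_spec()) {
  vals_mat <- if (inherits(intensity, "intensity_image")) intensity$values
              else intensity
  if (is.null(domain)) domain <- matrix(TRUE, nrow(vals_mat), ncol(vals_mat))
  stopifnot(identical(dim(domain), dim(vals_mat)))
  v <- vals_mat[domain]
  if (length(v) < 2L)
    stop_degenerate("contrast split needs at least 2 pixels in the domain")
  if (diff(range(v)) == 0)
    stop_degenerate("constant-intensity domain: no contrast to split")
  qs <- stats::quantile(v, c(search$lower_pct, search$upper_pct), names = FALSE)
  cand <- seq(qs[1], qs[2], length.out = search$n_candidates)
  sc <- contrast_objective(v, cand, search$objective)
  if (all(!is.finite(sc$obj)))
    stop_degenerate("no candidate threshold separates the domain")
  best <- which.max(sc$obj)  # first (lowest) threshold on ties
  if (sc$contrast[best] < search$min_contrast)
    stop_degenerate("no split reaches the minimum class contrast")
  thr <- cand[best]
  bright <- domain & (vals_mat >= thr)
  dark <- domain & (vals_mat < thr)
  structure(list(threshold = thr, bright_mask = bright, dark_mask = dark,
                 objective_value = sc$obj[best],
                 mean_contrast = sc$contrast[best]),
            class = "contrast_split_result")
}

# Objective and mean-contrast values of all candidate thresholds at once
# (sorted cumsum scan). Candidates leaving either side empty get -Inf.
contrast_objective <- function(v, cand, objective) {
  sv <- sort(v)
  cs <- cumsum(sv)
  n <- length(sv)
  k <- findInterval(cand, sv, left.open = TRUE)  # pixels strictly below t
  dark_mean <- ifelse(k > 0, cs[pmax(k, 1)] / k, NA_real_)
  bright_mean <- ifelse(k < n, (cs[n] - ifelse(k > 0, cs[pmax(k, 1)], 0)) /
                          (n - k), NA_real_)
  contrast <- bright_mean - dark_mean
  w_dark <- k / n
  obj <- switch(objective,
                between_class_variance = w_dark * (1 - w_dark) * contrast^2,
                mean_diff = contrast,
                mean_ratio = bright_mean / pmax(dark_mean, .Machine$double.eps))
  obj[k == 0 | k == n] <- -Inf
  contrast[k == 0 | k == n] <- -Inf
  list(obj = obj, contrast = contrast)
}

#' Multi-resolution segmentation parameters
#'
#' Defaults follow the standard parameterization for 8-bit imagery:
#' scale 50, shape weight 0.2, compactness weight 0.5.
#'
#' @param scale Positive stopping scale; merging stops when no admissible
#'   merge increases heterogeneity by less than `scale^2`.
#' @param shape_weight Weight of shape vs color heterogeneity, in `[0, 1)`.
#' @param compactness_weight Weight of compactness vs smoothness within the
#'   shape term, in `[0, 1]`.
#' @param connectivity Pixel connectivity, 4 (default) or 8.
#' @param channel_weights Positive per-channel weights (recycled).
#' @return An object of class `mrs_params`.
#' @export
mrs_params <- function(scale = 50, shape_weight = 0.2,
                       compactness_weight = 0.5, connectivity = 4L,
                       channel_weights = 1) {
  stopifnot(scale > 0, shape_weight >= 0, shape_weight < 1,
            compactness_weight >= 0, compactness_weight <= 1,
            connectivity %in% c(4L, 8L), all(channel_weights > 0))
  structure(list(scale = scale, shape_weight = shape_weight,
                 compactness_weight = compactness_weight,
                 connectivity = as.integer(connectivity),
                 channel_weights = channel_weights),
            class = "mrs_params")
}

#' Multi-resolution region-merging segmentation
#'
#' Bottom-up pairwise region merging starting from single pixels. The cost of
#' merging regions a and b is
#' `f = (1 - shape_weight) * dh_color + shape_weight * dh_shape`, where the
#' color term is the size-weighted increase in per-channel standard
#' deviation, and the shape term mixes compactness (`perimeter / sqrt(n)`)
#' and smoothness (`perimeter / bounding-box perimeter`), each weighted by
#' region size. Merging proceeds by local mutual-best-fitting in a seeded
#' scan order (ties to lower cost, then the smaller region id) and stops when
#' no merge has `f < scale^2`. The result is deterministic for a fixed seed.
#'
#' Channel values are multiplied by `dn_scale` before merging; the default of
#' 255 puts unit-range imagery on the 8-bit digital-number scale on which the
#' conventional scale parameter (50) is defined.
#'
#' @param channels An `intensity_image`, a numeric matrix, or a list of
#'   numeric matrices sharing one shape.
#' @param params An [mrs_params()] object.
#' @param seed Integer seed fixing the scan order.
#' @param domain Optional logical matrix; pixels outside get label 0.
#' @param dn_scale Multiplier applied to channel values before merging
#'   (default 255; use 1 for channels already on the intended scale).
#' @return A list of class `segment_map` with `labels` (integer matrix,
#'   0 outside the domain, segments numbered 1..n in row-major order of first
#'   appearance) and `n_segments`.
#' @export
multiresolution_segmentation <- function(channels, params = mrs_params(),
                                         seed = 1L, domain = NULL,
                                         dn_scale = 255) {
  if (inherits(channels, "intensity_image")) channels <- channels$values
  if (is.matrix(channels)) channels <- list(channels)
  stopifnot(length(channels) >= 1L)
  d <- dim(channels[[1]])
  for (ch in channels) stopifnot(identical(dim(ch), d))
  if (is.null(domain)) domain <- matrix(TRUE, d[1], d[2])
  stopifnot(identical(dim(domain), d))
  if (!any(domain)) stop_validation("empty segmentation domain")
  w <- rep_len(params$channel_weights, length(channels))
  chans <- lapply(channels, function(m) m * dn_scale)
  perm <- with_local_seed(seed, sample.int(d[1] * d[2]))
  lab <- cpp_mrs(chans, as.numeric(w), domain, perm,
                 params$scale, params$shape_weight,
                 params$compactness_weight, params$connectivity)
  structure(list(labels = lab, n_segments = attr(lab, "n_segments")),
            class = "segment_map")
}

#' Label connected components of a binary mask
#'
#' @param mask Logical matrix.
#' @param connectivity 4 (default) or 8.
#' @return A `segment_map` with components numbered 1..n in row-major order
#'   of first appearance; an empty mask gives `n_segments = 0`.
#' @export
merge_connected <- function(mask, connectivity = 4L) {
  stopifnot(is.logical(mask), is.matrix(mask), connectivity %in% c(4L, 8L))
  lab <- cpp_label_components(mask, as.integer(connectivity))
  structure(list(labels = lab, n_segments = attr(lab, "n_segments")),
            class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("<segment_map: %d x %d px, %d segments>\n",
              nrow(x$labels), ncol(x$labels), x$n_segments))
  invisible(x)
}

#' Write a segment debug table
#'
#' @param seg A `segment_map`.
#' @param intensity Matching `intensity_image` or matrix.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_segment_table <- function(seg, intensity, path) {
  vals <- if (inherits(intensity, "intensity_image")) intensity$values else
    intensity
  idx <- seg$labels > 0
  n_px <- tabulate(seg$labels[idx], nbins = seg$n_segments)
  means <- as.numeric(rowsum(vals[idx], seg$labels[idx])) / n_px
  utils::write.csv(data.frame(id = seq_len(seg$n_segments), n_pixels = n_px,
                              mean_intensity = means),
                   path, row.names = FALSE)
  invisible(path)
}
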