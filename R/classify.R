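#' Rule-set parameters for scene classification
#'
#' Defaults reproduce the published rule set: a 1000-pixel minimum iceberg
#' size at the 0.04 m survey resolution (1.6 m2, the smallest floe that can
#' support a hauled-out harbor seal), a GLCM homogeneity threshold of 0.45
#' separating water from brash ice, multi-resolution segmentation at scale
#' 50 / shape 0.2 / compactness 0.5, and a second contrast split that breaks
#' up "false icebergs" (clumps of small fragments bright enough to pass the
#' first split).
#'
#' The pixel floor is tied to the biological 1.6 m2 constant: at pixel sizes
#' other than 0.04 m the effective pixel threshold is
#' `max(min_iceberg_m2, min_iceberg_px * 0.04^2) / pixel_size^2`, so the
#' area floor governs at any resolution and raising `min_iceberg_px` is
#' monotone everywhere.
#'
#' @param min_iceberg_px Minimum iceberg size in reference 0.04 m pixels
#'   (default 1000).
#' @param min_iceberg_m2 Minimum iceberg area in m2 (default 1.6).
#' @param water_homogeneity_max Objects smoother than this GLCM homogeneity
#'   cutoff are classified as water (default 0.45).
#' @param mrs An [mrs_params()] object.
#' @param contrast_search A [threshold_search_spec()].
#' @param glcm A [glcm_spec()].
#' @param second_split Run the second contrast split on candidate icebergs
#'   (default `TRUE`).
#' @param connectivity Component connectivity, 4 (default) or 8.
#' @param seed Integer seed for the segmentation scan order.
#' @return An object of class `rule_set_params`.
#' @export
rule_set_params <- function(min_iceberg_px = 1000L, min_iceberg_m2 = 1.6,
                            water_homogeneity_max = 0.45,
                            mrs = mrs_params(),
                            contrast_search = threshold_search_spec(),
                            glcm = glcm_spec(),
                            second_split = TRUE, connectivity = 4L,
                            seed = 1L) {
  stopifnot(min_iceberg_px > 0, min_iceberg_m2 > 0,
            water_homogeneity_max > 0, water_homogeneity_max < 1,
            inherits(mrs, "mrs_params"),
            inherits(contrast_search, "threshold_search_spec"),
            inherits(glcm, "glcm_spec"),
            connectivity %in% c(4L, 8L))
  structure(list(min_iceberg_px = as.integer(min_iceberg_px),
                 min_iceberg_m2 = min_iceberg_m2,
                 water_homogeneity_max = water_homogeneity_max,
                 mrs = mrs, contrast_search = contrast_search, glcm = glcm,
                 second_split = isTRUE(second_split),
                 connectivity = as.integer(connectivity),
                 seed = as.integer(seed)),
            class = "rule_set_params")
}

# Effective minimum iceberg size in pixels at a given pixel size.
effective_min_px <- function(params, pixel_size_m) {
  floor_m2 <- max(params$min_iceberg_m2, params$min_iceberg_px * 0.04^2)
  as.integer(ceiling(floor_m2 / pixel_size_m^2 - 1e-9))
}

#' Classify one scene into icebergs, brash ice and water
#'
#' Runs the full rule set on a scene:
#' \enumerate{
#'   \item derive the intensity channel;
#'   \item contrast-split the (non-excluded) domain into bright and dark
#'     pixels; bright pixels become candidate icebergs, dark pixels are left
#'     unclassified;
#'   \item merge candidate pixels into connected components and revert
#'     components below the minimum iceberg size to unclassified;
#'   \item segment the unclassified domain by multi-resolution region
#'     merging;
#'   \item label each segment water if its GLCM homogeneity is below the
#'     water cutoff (smooth for the scene's texture scale), else brash ice;
#'     segments too small for any co-occurring pair default to brash, the
#'     mixed class;
#'   \item if enabled, contrast-split each surviving candidate component a
#'     second time: dark sub-objects become brash ice, bright sub-components
#'     are re-filtered by the size floor (failures become brash) and the
#'     survivors are the final icebergs, with geometry attached.
#' }
#' A fully dark scene yields zero icebergs without error. Every non-excluded
#' pixel carries exactly one class on return.
#'
#' @param scene A [scene_image()].
#' @param params A [rule_set_params()] object.
#' @return A list of class `scene_classification` with `class_map` (integer
#'   matrix using the [ice_classes()] palette, with the pixel size attached
#'   as attribute `pixel_size_m`) and `objects` (list of iceberg objects,
#'   each with `object_id`, `pixels` (linear indices), `n_pixels`,
#'   `area_m2`, `perimeter_m`, `angularity`, `enclosing_rect`).
#' @export
classify_scene <- function(scene, params = rule_set_params()) {
  stopifnot(inherits(scene, "scene_image"),
            inherits(params, "rule_set_params"))
  d <- dim(scene$pixels)[1:2]
  domain <- if (is.null(scene$exclusion_mask)) matrix(TRUE, d[1], d[2]) else
    !scene$exclusion_mask
  if (!any(domain)) stop_validation("scene domain is fully excluded")
  ps <- scene$pixel_size_m
  min_px <- effective_min_px(params, ps)
  cls <- ice_classes()

  inten <- rgb_to_intensity(scene)
  vals <- inten$values
  scene_rng <- range(vals[domain])

  # (2) first contrast split; a constant dark domain is all-dark
  split1 <- tryCatch(contrast_split(inten, domain, params$contrast_search),
                     icehab_degenerate_error = function(e) NULL)
  bright <- if (is.null(split1)) matrix(FALSE, d[1], d[2]) else
    split1$bright_mask

  # (3) candidate iceberg components; small ones revert to unclassified
  cand <- merge_connected(bright, params$connectivity)
  keep_comp <- integer(0)
  if (cand$n_segments > 0L) {
    sizes <- tabulate(cand$labels[cand$labels > 0L], nbins = cand$n_segments)
    keep_comp <- which(sizes >= min_px)
  }
  cand_kept <- cand$labels > 0L & cand$labels %in% keep_comp
  unclass <- domain & !cand_kept

  class_map <- matrix(cls[["excluded"]], d[1], d[2])

  # (4)-(5) segment the unclassified domain; water vs brash by texture
  if (any(unclass)) {
    seg <- multiresolution_segmentation(inten, params$mrs, seed = params$seed,
                                        domain = unclass)
    hom <- segment_homogeneity(vals, seg$labels, params$glcm, scene_rng)
    is_water <- !is.na(hom) & hom < params$water_homogeneity_max
    lab <- seg$labels
    water_px <- lab > 0L & is_water[pmax(lab, 1L)]
    class_map[unclass] <- cls[["brash"]]
    class_map[water_px] <- cls[["water"]]
  }

  # (6) second contrast split within each surviving candidate component
  iceberg_mask <- matrix(FALSE, d[1], d[2])
  for (k in keep_comp) {
    comp_mask <- cand$labels == k
    bright_sub <- comp_mask
    if (params$second_split) {
      sp <- tryCatch(contrast_split(vals, comp_mask, params$contrast_search),
                     icehab_degenerate_error = function(e) NULL)
      # constant component: nothing to strip, keep it whole
      if (!is.null(sp)) bright_sub <- sp$bright_mask
    }
    class_map[comp_mask & !bright_sub] <- cls[["brash"]]
    sub <- merge_connected(bright_sub, params$connectivity)
    if (sub$n_segments > 0L) {
      ssz <- tabulate(sub$labels[sub$labels > 0L], nbins = sub$n_segments)
      ok <- which(ssz >= min_px)
      survivors <- sub$labels > 0L & sub$labels %in% ok
      class_map[bright_sub & !survivors] <- cls[["brash"]]
      iceberg_mask <- iceberg_mask | survivors
    }
  }
  class_map[iceberg_mask] <- cls[["iceberg"]]

  # final iceberg objects with geometry
  objects <- list()
  if (any(iceberg_mask)) {
    final <- merge_connected(iceberg_mask, params$connectivity)
    for (k in seq_len(final$n_segments)) {
      m <- final$labels == k
      rect <- min_enclosing_rect(m)
      objects[[k]] <- list(
        object_id = k,
        pixels = which(m),
        n_pixels = sum(m),
        area_m2 = object_area(m, ps),
        perimeter_m = object_perimeter(m, ps),
        angularity = crack_edges(m) / rect$perimeter_px,
        enclosing_rect = rect)
    }
  }
  attr(class_map, "pixel_size_m") <- ps
  structure(list(class_map = class_map, objects = objects,
                 scene_id = scene$scene_id),
            class = "scene_classification")
}

#' Classify a survey of scenes
#'
#' Classifies each scene independently; a failure on one scene is recorded
#' and skipped rather than aborting the batch. An error is raised only if
#' every scene fails.
#'
#' @param scenes List of [scene_image()] objects.
#' @param params A [rule_set_params()] object.
#' @return A list with one element per scene: either a list with
#'   `classification` (see [classify_scene()]) and `stats` (see
#'   [scene_stats()]), or a list with `error` (the failure message).
#' @export
classify_survey <- function(scenes, params = rule_set_params()) {
  stopifnot(length(scenes) >= 1L)
  out <- lapply(scenes, function(sc) {
    tryCatch({
      cl <- classify_scene(sc, params)
      list(scene_id = sc$scene_id, classification = cl,
           stats = scene_stats(cl$class_map, cl$objects, sc$pixel_size_m,
                               scene_id = sc$scene_id))
    }, error = function(e) {
      list(scene_id = sc$scene_id, error = conditionMessage(e))
    })
  })
  if (all(vapply(out, function(x) !is.null(x$error), logical(1))))
    stop_validation("all scenes failed to classify")
  out
}
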