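---
title: "Quantifying floating glacier-ice habitat with object-based image analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying floating glacier-ice habitat with object-based image analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icehab)
```

## The problem

Tidewater glaciers calve icebergs into their fjords, and those icebergs are
habitat: harbor seals haul out on floating ice to rest, pup, and molt. A
floe must be large enough to carry a seal — about 1.6 m², derived from adult
body length — so the habitat question is not just "how much ice" but "how
much ice in pieces of at least 1.6 m², of what size and shape, and where in
the fjord". `icehab` answers that question from non-overlapping aerial RGB
frames (about 80 × 120 m at a standardized 0.04 m pixel) with an
object-based image analysis (OBIA) rule set, and attaches survey-level
aggregation, uncertainty, and accuracy assessment.

Three classes partition every classified pixel:

* **iceberg** — connected floating ice of at least 1.6 m² (1000 pixels at
  0.04 m), potential haul-out substrate;
* **brash ice** — ice in pieces smaller than 1.6 m²; at object level a
  mixture of ice and water pixels;
* **water** — open water.

## The rule set

`classify_scene()` runs, in order:

1. **Intensity.** The RGB frame is reduced to the intensity component of
   the IHS transform, `(R + G + B) / 3`; the three channels are strongly
   correlated in this imagery and one channel suffices to separate light
   and dark features.
2. **First contrast split.** `contrast_split()` picks an intensity
   threshold from a candidate grid (25 values between the 1st and 99th
   domain percentiles) maximizing the contrast between the bright and dark
   classes. Bright pixels become candidate icebergs; dark pixels stay
   unclassified.
3. **Size filter.** Candidate pixels are merged into connected components
   (4-connectivity by default, so brash fragments do not leak together
   diagonally) and components below the floor revert to unclassified.
4. **Multi-resolution segmentation** of the unclassified domain
   (`multiresolution_segmentation()`, scale 50, shape 0.2, compactness
   0.5).
5. **Texture rule.** Per segment, GLCM homogeneity
   `sum P(i,j) / (1 + (i-j)^2)` decides water (`< 0.45`) versus brash.
   At centimeter pixels, open water carries pixel-scale ripple and glint
   speckle, so its co-occurrence mass sits off the diagonal and its
   homogeneity is *low*; locally flat ice surfaces score high. This is the
   only reading under which the published water rule ("smooth objects,
   homogeneity < 0.45, are water") is self-consistent, and the synthetic
   generator renders water accordingly. Segments too small to contain any
   co-occurring pair default to brash, the mixed class.
6. **Second contrast split.** Small fragments packed closely enough can
   pass step 2 as one bright "false iceberg". Each surviving candidate is
   therefore split once more (water segments are excluded by
   construction); dark sub-objects become brash and the remaining bright
   components are re-filtered by the size floor. The published workflow
   does not say whether the floor is re-applied after this split; it is
   re-applied here, otherwise sub-floor bright shards would survive as
   icebergs and contradict the 1.6 m² definition.

Per final iceberg, the package reports area (pixel count × pixel area),
crack perimeter, the minimum-perimeter enclosing rotated rectangle, and
**angularity** — perimeter over enclosing-rectangle perimeter, ≥ 1 for
compact shapes and growing with raggedness.

## Contrast-split details

The split objective is Otsu's between-class variance
`w_d · w_b · (μ_b − μ_d)²` by default. An unweighted mean difference
`μ_b − μ_d` (selectable as `objective = "mean_diff"`) is degenerate on
skewed compositions: when one class is rare, the objective is maximized by
splitting off a handful of extreme pixels — on water-dominated frames it
prefers isolating the brightest percent of iceberg cores over the
water/ice boundary, destroying every iceberg in roughly a third of
high-contrast test scenes. The weighted criterion is the standard
formalization of "maximize the contrast between the two classes" and picks
the class boundary robustly.

A split is only *accepted* if the resulting classes differ by at least
`min_contrast` (default 0.25 intensity units, about half the typical
water–ice reflectance contrast). A homogeneous noisy field always admits
some maximizer — for Gaussian speckle the best split sits near a sample
extreme with a spurious contrast of roughly 2.7σ (≈ 0.22 at water noise
σ = 0.08) — and without the floor an all-water frame would promote almost
the whole scene to a candidate iceberg. The floor also leaves genuine
near-constant icebergs whole in step 6 (their internal rim/core contrast is
≈ 0.1) while still shattering mixed-pixel false icebergs (gap/fragment
contrast ≥ 0.3). Ties in the threshold search break toward the lowest
candidate.

Degenerate domains (constant intensity, or no admissible split) raise a
typed condition; the rule set maps it to "all dark" in step 2 and "keep the
candidate whole" in step 6.

## Multi-resolution segmentation details

Segmentation is bottom-up pairwise region merging from single pixels. The
cost of merging regions *a* and *b* is

```
f = (1 − w_shape) · Δh_color + w_shape · Δh_shape
Δh_color  = Σ_c w_c (n_m σ_m − n_a σ_a − n_b σ_b)
Δh_shape  = w_cmpct · Δh_cmpct + (1 − w_cmpct) · Δh_smooth
Δh_cmpct  = p_m √n_m − p_a √n_a − p_b √n_b
Δh_smooth = n_m p_m / b_m − n_a p_a / b_a − n_b p_b / b_b
```

with `n` the pixel count, `σ` the per-channel standard deviation, `p` the
crack perimeter and `b` the bounding-box perimeter. Merging proceeds by
*local mutual best fitting*: regions are visited in a seeded random scan
order (fixed by the `seed` argument, so results are bit-reproducible);
a region merges with its cheapest neighbor only if it is, reciprocally,
that neighbor's cheapest partner and the cost is below `scale²`. Ties
break toward lower cost, then the smaller region id; merged regions keep
the smaller id. Sweeps repeat until no admissible merge remains.

Two conventions matter:

* **Digital-number scale.** Channel values are multiplied by `dn_scale`
  (default 255) before merging. The conventional scale parameter of 50 is
  defined on 8-bit digital numbers; on unit-range data `scale = 50` would
  never stop merging.
* **Exact merge order of the original commercial implementation is
  unpublished**; this package pins down its own deterministic order (above)
  and guarantees only the stated cost model. The test suite checks the
  engine against a from-scratch greedy re-implementation on small random
  instances.

By default the merge runs on the intensity channel only, matching the rule
set's use of a single channel; RGB channels with weights are supported.

## Texture and geometry conventions

* GLCM quantization is **global per scene** (32 levels over the scene's
  intensity range), not per object, so the 0.45 threshold is comparable
  across objects; offsets default to the four standard directions and
  pairs must lie entirely inside the object (no bleed across borders).
  The published workflow states neither quantization depth nor offsets;
  both are configurable assumptions here.
* The perimeter convention is the **crack boundary** (count of exposed
  pixel edges × pixel size). A Euclidean contour perimeter would give
  convex shapes angularity below 1, contradicting the reported range of
  the statistic (mean 1.8, maximum 4.7); the crack convention makes a
  filled axis-aligned rectangle exactly 1 and roughness strictly
  increasing.
* The "smallest rectangle that can enclose the object" is the
  minimum-perimeter **rotated** rectangle over the convex hull of pixel
  centers (rotating calipers; the optimum is flush with a hull edge), with
  each side padded by one pixel so the rectangle covers pixel extents and
  degenerate one-pixel or collinear objects stay well-defined. An
  axis-aligned variant is available by argument.
* `min_iceberg_px` is interpreted as an area floor expressed in reference
  0.04 m pixels: the effective pixel floor at pixel size `s` is
  `max(min_iceberg_m2, min_iceberg_px · 0.04²) / s²`. The biological
  1.6 m² constant therefore governs at any resolution, and raising the
  pixel floor is monotone everywhere.

## Survey aggregation and uncertainty

`scene_stats()` reports per-frame percentages over the non-excluded area
(summing to 100 exactly), iceberg counts, mean size and mean angularity;
`aggregate_survey()` summarizes per-variable mean, sample SD (n − 1; 0 by
convention for a single frame), maximum and image count, with equal
per-scene weighting. `extrapolate_fjord()` multiplies the survey-mean
iceberg percentage by the fjord water area. Two uncertainty sources —
classification (default 26%, the observed underestimate of iceberg area
against manually corrected objects) and edge-of-frame scale distortion
(default 7%; `scale_distortion_bound()` gives a flying-height bound
`1/cos²θ − 1`, below 7% at 308 m) — combine in **quadrature** (≈ 27%); an
arithmetic sum (33%) is inconsistent with the survey's published combined
figure and would overstate independent errors. The combined fraction is
rounded to two decimals by default, matching how the published arithmetic
propagates it. `representativeness_resample()` draws seeded trials of
frames without replacement (100 trials of 40 frames in the original
protocol) and also returns the analytic standard error of the mean
fraction, `sd(fraction)/√n` — the SE formula is an assumption, as the
source states the value without one. `interpolate_map()` grids scene
values with an exact thin-plate-spline RBF (surface passes through every
measured point; linear fields reproduce to 1e−6).

## Accuracy assessment

`sample_points()` samples up to 100 points per class per frame, stratified
by the reference map by default ("each class *where present*"; the
alternative stratification by the automated map is an option, since the
protocol sentence is ambiguous). `confusion_matrix()` arranges classified
rows × reference columns; `accuracy_metrics()` reports overall, user's
(row-wise) and producer's (column-wise) accuracy with commission/omission
complements and the full cross-error table; `cohens_kappa()` the
chance-corrected agreement; `collapse_classes()` merges the two ice
classes to assess ice-versus-water performance. Percentages print to one
decimal and kappa to two in the CSV writers.

## What the synthetic generator emulates — and what it does not

`generate_scene()` renders seeded frames with exact ground truth recorded
before noise: dark water (mean 0.15) with pixel-scale speckle (σ 0.08) and
a smooth illumination plane; bright, locally flat brash fragments
(intensity 0.70, each below 1.6 m²); and icebergs (intensity 0.85) as
radially perturbed ellipses whose roughness parameter raises expected
angularity, with a thin darker waterline rim (up to 12% darkening over the
outer tenth of the radius) as wetted ice margins show. Default frame
geometry and composition emulate the survey conditions: ~80 × 120 m at
0.04 m/pixel, lognormal iceberg sizes of mean 5.7 m² (SD 2.6 m²), brash
cover decaying from ~0.9 near the terminus to ~0.02 at 11 km
(`default_brash_gradient()`), a few percent iceberg cover.

Two constraints keep the truth identifiable against the class
definitions: fragments keep a small open-water buffer around icebergs, and
fragment placement rejects any connected brash clump reaching 80% of the
iceberg floor — a connected ice body of 1.6 m² *is* an iceberg by
definition, so truth labels straddling that boundary would make count
recovery ill-posed rather than wrong. A consequence is that the generator
cannot pack brash beyond roughly half coverage under the clump constraint;
true mélange (persistent, fused brash cover) is exactly the regime the
method does not claim to resolve.

The generator has no sun glint model, no sediment-covered or dark ice, no
partial icebergs at frame edges, and no photorealistic shading. Passing
end-to-end tests therefore demonstrates that the rule set recovers objects
whose contrast and texture match its assumptions — not performance on real
imagery with low ice/water contrast or densely fused ice, where the
original survey itself reports icebergs misclassified as brash about 20%
of the time.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on
desk-scale frames (180 × 270 px at 0.12 m/pixel, i.e. 21.6 × 32.4 m, with
the same intensity model as the full-size defaults), 20–30 frames per run;
oracle comparisons use 8 × 8 (region merging, against a from-scratch
greedy implementation) and 16 × 16 (threshold search, against exhaustive
scan) instances. At pixel sizes other than 0.04 m the m² floor governs the
size filter, so the scaled-down frames exercise the identical rule set.
All randomness flows from explicit integer seeds; re-running any function
with the same inputs and seed is bit-identical. Degenerate inputs
(constant domains, empty masks, objects with no co-occurring pair,
all-mass-in-one-cell confusion matrices) are mapped to typed conditions or
documented defaults rather than NaNs.

## Known limitations

* Label rasters are written as PNG with a JSON georeferencing sidecar
  rather than GeoTIFF; round-trips are exact, but GIS import needs the
  sidecar. Iceberg outlines export as GeoJSON (local meters, or lon/lat by
  a local meters-per-degree approximation — no map projections).
* Equivalence with the original commercial OBIA software cannot be
  guaranteed: its contrast-split objective and merge order are
  unpublished. The package documents and tests its own cost models.
* Whether enhancement should precede or follow resampling to 0.04 m is
  unstated in the source protocol; the pipeline resamples first
  (configurable ordering by calling the steps directly).
* No seal detection, no kriging, no tidal drift correction, no
  area-weighted (Olofsson-style) accuracy adjustment.
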