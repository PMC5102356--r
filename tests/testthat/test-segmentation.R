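test_that("contrast split separates a two-level image and honors the mask contract", {
  v <- matrix(c(rep(0.2, 128), rep(0.8, 128)), 16, 16)
  cs <- contrast_split(v)
  expect_true(cs$threshold > 0.2 && cs$threshold <= 0.8)
  expect_equal(sum(cs$bright_mask), 128L)
  expect_true(all(v[cs$bright_mask] == 0.8))
  expect_false(any(cs$bright_mask & cs$dark_mask))
  expect_true(all(cs$bright_mask | cs$dark_mask))
  expect_equal(cs$mean_contrast, 0.6)
  expect_equal(cs$objective_value, 0.5 * 0.5 * 0.6^2)
  expect_true(all(v[cs$bright_mask] >= cs$threshold))
  expect_true(all(v[cs$dark_mask] < cs$threshold))
})

test_that("contrast split equals the exhaustive-threshold oracle on mixtures", {
  for (seed in 1:6) {
    img <- make_mixture_image(seed = seed)
    cs <- contrast_split(img)
    ora <- oracle_contrast_split(img)
    expect_identical(cs$bright_mask, ora$bright_mask)
    expect_equal(cs$objective_value, ora$objective, tolerance = 1e-12)
  }
})

test_that("contrast split objective is maximal over its candidate grid", {
  img <- make_mixture_image(seed = 11)
  search <- threshold_search_spec()
  cs <- contrast_split(img, search = search)
  v <- sort(img)
  qs <- quantile(v, c(search$lower_pct, search$upper_pct), names = FALSE)
  for (t in seq(qs[1], qs[2], length.out = search$n_candidates)) {
    bright <- v >= t
    if (!any(bright) || all(bright)) next
    w <- mean(bright)
    expect_lte(w * (1 - w) * (mean(v[bright]) - mean(v[!bright]))^2,
               cs$objective_value + 1e-12)
  }
})

test_that("degenerate contrast-split domains raise a degenerate-input condition", {
  expect_error(contrast_split(matrix(0.4, 8, 8)),
               class = "icehab_degenerate_error")
  # domain masking out all bright pixels leaves a constant field
  v <- matrix(0.2, 8, 8); v[1:2, ] <- 0.9
  expect_error(contrast_split(v, domain = v < 0.5),
               class = "icehab_degenerate_error")
  # speckle without structure falls below the minimum-contrast floor
  noise <- withr::with_seed(5, matrix(pmin(pmax(rnorm(400, 0.15, 0.05), 0), 1),
                                      20, 20))
  expect_error(contrast_split(noise), class = "icehab_degenerate_error")
  # ... but is accepted when the floor is disabled
  cs <- contrast_split(noise, search = threshold_search_spec(min_contrast = 0))
  expect_s3_class(cs, "contrast_split_result")
})

test_that("multi-resolution segmentation handles flat and two-region images", {
  expect_equal(multiresolution_segmentation(matrix(0.5, 16, 16),
                                            seed = 1)$n_segments, 1L)
  img <- cbind(matrix(0.2, 16, 8), matrix(0.7, 16, 8))
  s <- multiresolution_segmentation(img, mrs_params(scale = 50), seed = 1)
  expect_equal(s$n_segments, 2L)
  # hand-check: the cross-boundary color cost alone exceeds scale^2
  dn <- 0.5 * 255
  sigma_merged <- dn / 2
  expect_gt(256 * sigma_merged, 50^2)
  expect_error(multiresolution_segmentation(img, domain = matrix(FALSE, 16, 16)),
               class = "icehab_validation_error")
})

test_that("region merging matches the brute-force greedy oracle, incl. 8-connectivity and masked domains", {
  for (case in 1:4) {
    seed <- 20 + case
    img <- withr::with_seed(seed, matrix(runif(64), 8, 8))
    conn <- if (case %% 2 == 0) 8L else 4L
    dom <- matrix(TRUE, 8, 8)
    if (case == 3) dom[1:3, 1:2] <- FALSE
    scl <- c(15, 25, 40, 25)[case]
    s <- multiresolution_segmentation(
      img, mrs_params(scale = scl, connectivity = conn), seed = seed,
      domain = dom)
    perm <- withr::with_seed(seed, sample.int(64))
    ora <- oracle_mrs(img * 255, 1, dom, perm, scl, connectivity = conn)
    expect_equal(matrix(as.integer(s$labels), 8, 8), ora$labels)
  }
})

test_that("segmentation is deterministic, connected, and coarsens with scale", {
  img <- withr::with_seed(31, matrix(runif(32 * 32), 32, 32))
  img[8:20, 8:20] <- img[8:20, 8:20] + 0.4
  a <- multiresolution_segmentation(img, mrs_params(scale = 30), seed = 5)
  b <- multiresolution_segmentation(img, mrs_params(scale = 30), seed = 5)
  expect_identical(a$labels, b$labels)
  # every segment is connected under the configured connectivity
  for (k in seq_len(a$n_segments)) {
    expect_equal(oracle_components(a$labels == k, 4L)$n, 1L)
  }
  # labels form the contiguous set 1..n
  expect_setequal(unique(as.vector(a$labels)), seq_len(a$n_segments))
  counts <- vapply(c(10, 30, 60, 120), function(scl)
    multiresolution_segmentation(img, mrs_params(scale = scl),
                                 seed = 5)$n_segments, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("sufficient scale recovers a noiseless cartoon exactly", {
  img <- matrix(0.1, 30, 30)
  img[5:15, 5:15] <- 0.5
  img[20:28, 18:28] <- 0.9
  s <- multiresolution_segmentation(img, mrs_params(scale = 40,
                                                    shape_weight = 0),
                                    seed = 2)
  expect_equal(s$n_segments, 3L)
  truth <- matrix(1L, 30, 30)
  truth[5:15, 5:15] <- 2L
  truth[20:28, 18:28] <- 3L
  # identical partitions up to label naming
  expect_equal(length(unique(paste(s$labels, truth))), 3L)
})

test_that("connected-component labeling agrees with flood fill", {
  expect_equal(merge_connected(matrix(FALSE, 5, 5))$n_segments, 0L)
  diagm <- matrix(FALSE, 4, 4); diagm[1, 1] <- TRUE; diagm[2, 2] <- TRUE
  expect_equal(merge_connected(diagm, 4L)$n_segments, 2L)
  expect_equal(merge_connected(diagm, 8L)$n_segments, 1L)
  for (seed in 1:4) {
    m <- withr::with_seed(seed, matrix(runif(15 * 15) < 0.45, 15, 15))
    for (conn in c(4L, 8L)) {
      got <- merge_connected(m, conn)
      ora <- oracle_components(m, conn)
      expect_equal(got$n_segments, ora$n)
      expect_equal(length(unique(paste(as.vector(got$labels),
                                       as.vector(ora$labels)))),
                   ora$n + (if (any(!m)) 1L else 0L))
    }
  }
})
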