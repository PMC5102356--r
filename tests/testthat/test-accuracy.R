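test_that("stratified point sampling is seeded, capped, and skips absent classes", {
  cls <- ice_classes()
  truth <- matrix(cls[["water"]], 30, 30)
  truth[1:5, 1:10] <- cls[["brash"]]   # 50 brash pixels
  auto <- truth
  auto[1, 1:5] <- cls[["water"]]       # a few disagreements
  s1 <- sample_points(auto, truth, n_per_class = 100, seed = 9)
  s2 <- sample_points(auto, truth, n_per_class = 100, seed = 9)
  expect_identical(s1, s2)
  expect_equal(sum(s1$truth == "brash"), 50L)     # capped at availability
  expect_equal(sum(s1$truth == "water"), 100L)
  expect_equal(sum(s1$truth == "iceberg"), 0L)    # absent stratum skipped
  expect_true(all(truth[cbind(s1$row, s1$col)] ==
                    cls[match(s1$truth, names(cls))]))
  expect_error(sample_points(auto[1:10, ], truth),
               class = "icehab_validation_error")
})

test_that("confusion matrices count samples and reject unknown labels", {
  s <- data.frame(auto = c("water", "water", "brash", "iceberg"),
                  truth = c("water", "brash", "brash", "brash"))
  cm <- confusion_matrix(s)
  expect_s3_class(cm, "confusion_matrix")
  expect_equal(sum(cm), 4)
  expect_equal(cm["water", "brash"], 1)
  expect_equal(cm["brash", "brash"], 1)
  expect_error(confusion_matrix(c("water"), c("lava")),
               class = "icehab_validation_error")
  single <- confusion_matrix(c("water"), c("water"))
  expect_equal(sum(single), 1)
})

test_that("accuracy metrics follow the row/column conventions", {
  ident <- as_confusion_matrix(diag(c(5, 7, 9)))
  m <- accuracy_metrics(ident)
  expect_equal(m$overall_pct, 100)
  expect_true(all(m$users_pct == 100) && all(m$producers_pct == 100))
  expect_true(all(m$commission_pct == 0) && all(m$omission_pct == 0))

  two <- as_confusion_matrix(matrix(c(3, 1, 1, 3), 2, 2,
                                    dimnames = list(c("a", "b"),
                                                    c("a", "b"))))
  m2 <- accuracy_metrics(two)
  expect_equal(m2$overall_pct, 75)
  expect_equal(unname(m2$users_pct), c(75, 75))
  expect_equal(unname(m2$producers_pct), c(75, 75))

  # an empty row gives NA for that class, not an error
  z <- as_confusion_matrix(matrix(c(4, 0, 2, 0), 2, 2,
                                  dimnames = list(c("a", "b"), c("a", "b"))))
  m3 <- accuracy_metrics(z)
  expect_true(is.na(m3$users_pct[["b"]]))
})

test_that("Cohen's kappa behaves at its anchor points and bounds", {
  perfect <- as_confusion_matrix(diag(c(10, 20, 30)))
  expect_equal(cohens_kappa(perfect), 1)
  # predicting one class for everything: agreement equals chance
  onerow <- as_confusion_matrix(matrix(c(6, 0, 4, 0), 2, 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b"))))
  expect_equal(cohens_kappa(onerow), 0)
  # all mass in one cell: undefined
  degen <- as_confusion_matrix(matrix(c(5, 0, 0, 0), 2, 2,
                                      dimnames = list(c("a", "b"),
                                                      c("a", "b"))))
  expect_true(is.na(cohens_kappa(degen)))
  # kappa <= overall accuracy; invariant under simultaneous permutation
  m <- withr::with_seed(6, matrix(rpois(9, 20) + diag(3) * 30, 3, 3))
  dimnames(m) <- list(c("w", "b", "i"), c("w", "b", "i"))
  cm <- as_confusion_matrix(m)
  k <- cohens_kappa(cm)
  expect_lte(k, accuracy_metrics(cm)$overall_pct / 100)
  p <- c(3, 1, 2)
  cmp <- as_confusion_matrix(m[p, p])
  expect_equal(cohens_kappa(cmp), k)
})

test_that("collapsing classes preserves the grand total", {
  m <- withr::with_seed(10, matrix(rpois(9, 15), 3, 3))
  dimnames(m) <- list(c("water", "brash", "iceberg"),
                      c("water", "brash", "iceberg"))
  cm <- as_confusion_matrix(m)
  idmap <- c(water = "water", brash = "brash", iceberg = "iceberg")
  expect_equal(unclass(collapse_classes(cm, idmap))[, ], unclass(cm)[, ])
  icemap <- c(water = "water", brash = "ice", iceberg = "ice")
  col <- collapse_classes(cm, icemap)
  expect_equal(sum(col), sum(cm))
  allmap <- c(water = "all", brash = "all", iceberg = "all")
  expect_equal(accuracy_metrics(collapse_classes(cm, allmap))$overall_pct,
               100)
})

test_that("the confusion CSV mirrors the matrix layout with margins", {
  d <- withr::local_tempdir()
  m <- as_confusion_matrix(matrix(c(8, 2, 1, 9), 2, 2,
                                  dimnames = list(c("water", "ice"),
                                                  c("water", "ice"))))
  p <- write_confusion_csv(m, file.path(d, "cm.csv"))
  back <- read.csv(p, row.names = 1)
  expect_equal(back["Total", "water"], 10)
  expect_equal(back["water", "Total"], 9)
})
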