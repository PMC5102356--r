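#' Stratified random point sampling for accuracy assessment
#'
#' For each class present in the reference (truth) map, samples up to
#' `n_per_class` pixels uniformly without replacement (seeded) and records
#' the automated and reference class at each point. Stratification is by
#' truth class by default; set `stratify_by = "auto"` to stratify by the
#' automated map instead. Classes absent from the stratifying map are simply
#' not sampled (no error); excluded pixels are never sampled.
#'
#' @param auto Integer class matrix from the automated classification.
#' @param truth Integer class matrix of reference labels (same shape).
#' @param n_per_class Target points per class (default 100).
#' @param seed Integer seed.
#' @param stratify_by `"truth"` (default) or `"auto"`.
#' @return Data frame with columns `row`, `col`, `auto`, `truth` (class
#'   names).
#' @export
sample_points <- function(auto, truth, n_per_class = 100L, seed = 1L,
                          stratify_by = c("truth", "auto")) {
  if (!identical(dim(auto), dim(truth)))
    stop_validation("auto and truth maps must share one shape")
  stratify_by <- match.arg(stratify_by)
  cls <- ice_classes()
  strata_map <- if (stratify_by == "truth") truth else auto
  class_codes <- cls[c("water", "brash", "iceberg")]
  picks <- with_local_seed(seed, {
    out <- list()
    for (nm in names(class_codes)) {
      idx <- which(strata_map == class_codes[[nm]] &
                   auto != cls[["excluded"]] & truth != cls[["excluded"]])
      if (length(idx) == 0L) next
      m <- min(n_per_class, length(idx))
      out[[nm]] <- if (length(idx) == 1L) idx else sample(idx, m)
    }
    out
  })
  idx <- unlist(picks, use.names = FALSE)
  if (is.null(idx)) idx <- integer(0)
  code_to_name <- stats::setNames(names(cls), cls)
  nr <- nrow(auto)
  data.frame(row = (idx - 1L) %% nr + 1L,
             col = (idx - 1L) %/% nr + 1L,
             auto = code_to_name[as.character(auto[idx])],
             truth = code_to_name[as.character(truth[idx])],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a confusion matrix
#'
#' Counts are arranged with classified classes as rows and reference (truth)
#' classes as columns, the layout of a standard error matrix.
#'
#' @param samples Data frame with columns `auto` and `truth` (from
#'   [sample_points()]), or a vector of classified labels.
#' @param truth Vector of reference labels (when `samples` is a vector).
#' @param classes Optional class-name ordering.
#' @return An integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(samples, truth = NULL, classes = NULL) {
  if (is.data.frame(samples)) {
    classified <- samples$auto
    truth <- samples$truth
  } else {
    classified <- samples
  }
  if (length(classified) < 1L)
    stop_validation("need at least one sample")
  if (length(classified) != length(truth))
    stop_validation("classified and truth labels differ in length")
  if (is.null(classes)) classes <- c("water", "brash", "iceberg")
  if (!all(c(classified, truth) %in% classes))
    stop_validation("unknown class label in samples")
  cm <- table(factor(classified, levels = classes),
              factor(truth, levels = classes))
  as_confusion_matrix(unclass(cm))
}

#' Mark a counts matrix as a confusion matrix
#'
#' @param counts Square numeric matrix, rows = classified classes, columns =
#'   reference classes, with matching dimnames.
#' @return The matrix with class `confusion_matrix`.
#' @export
as_confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop_validation("confusion matrix must be square")
  if (any(counts < 0)) stop_validation("counts must be non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- colnames(counts) <-
      paste0("class", seq_len(nrow(counts)))
  storage.mode(counts) <- "double"
  names(dimnames(counts)) <- c("classified", "truth")
  structure(counts, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- unclass(x)
  aug <- cbind(m, Total = rowSums(m))
  aug <- rbind(aug, Total = colSums(aug))
  print(aug)
  invisible(x)
}

#' Accuracy metrics from a confusion matrix
#'
#' Overall accuracy is the diagonal fraction; user's accuracy of a class is
#' the diagonal count over its row total (commission error is its
#' complement); producer's accuracy is the diagonal count over its column
#' total (omission error is its complement). Classes with an empty row or
#' column get NA for the affected metric rather than an error.
#'
#' @param cm A [confusion_matrix()].
#' @return A list with `overall_pct`, `users_pct`, `producers_pct`,
#'   `commission_pct`, `omission_pct` (named per class), and
#'   `cross_error_pct`, the full matrix of `counts[c, t] / column_total(t)`
#'   percentages (entry `[c, t]` is the share of true class `t` classified
#'   as `c`).
#' @export
accuracy_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- unclass(cm)
  total <- sum(m)
  if (total <= 0) stop_validation("confusion matrix is empty")
  rt <- rowSums(m)
  ct <- colSums(m)
  dg <- diag(m)
  users <- ifelse(rt > 0, dg / rt, NA_real_) * 100
  prods <- ifelse(ct > 0, dg / ct, NA_real_) * 100
  cross <- sweep(m, 2, ifelse(ct > 0, ct, NA_real_), "/") * 100
  list(overall_pct = 100 * sum(dg) / total,
       users_pct = users,
       producers_pct = prods,
       commission_pct = 100 - users,
       omission_pct = 100 - prods,
       cross_error_pct = cross)
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with
#' `p_e = sum_c row_total(c) * col_total(c) / N^2`. Undefined (NA) when all
#' mass sits in a single cell (`p_e = 1`).
#'
#' @param cm A [confusion_matrix()].
#' @return Kappa in `[-1, 1]`, or NA when undefined.
#' @export
cohens_kappa <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- unclass(cm)
  n <- sum(m)
  if (n <= 0) stop_validation("confusion matrix is empty")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Collapse confusion-matrix classes into superclasses
#'
#' Sums rows and columns into superclasses (e.g. merging the two ice classes
#' to assess ice-versus-water performance); the grand total is preserved.
#'
#' @param cm A [confusion_matrix()].
#' @param mapping Named character vector mapping every class to its
#'   superclass, e.g. `c(water = "water", brash = "ice", iceberg = "ice")`.
#' @return A collapsed [confusion_matrix()].
#' @export
collapse_classes <- function(cm, mapping) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- unclass(cm)
  if (!all(rownames(m) %in% names(mapping)))
    stop_validation("mapping must cover every class")
  sup <- unique(unname(mapping[rownames(m)]))
  out <- matrix(0, length(sup), length(sup), dimnames = list(sup, sup))
  for (i in rownames(m))
    for (j in colnames(m))
      out[mapping[[i]], mapping[[j]]] <- out[mapping[[i]], mapping[[j]]] +
        m[i, j]
  as_confusion_matrix(out)
}

#' Write a confusion matrix with margins as CSV
#'
#' Rows are classified classes with a total column and user's accuracy;
#' a totals row and producer's accuracies close the table.
#'
#' @param cm A [confusion_matrix()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  m <- unclass(cm)
  met <- accuracy_metrics(cm)
  df <- as.data.frame(m)
  df$Total <- rowSums(m)
  df$users_accuracy_pct <- round(met$users_pct, 1)
  tot <- c(colSums(m), sum(m), NA)
  prod <- c(round(met$producers_pct, 1), NA, round(met$overall_pct, 1))
  out <- rbind(df, Total = tot, producers_accuracy_pct = prod)
  utils::write.csv(out, path, row.names = TRUE)
  invisible(path)
}
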