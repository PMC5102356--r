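# Independent brute-force oracles and fixture builders. Every oracle here
# recomputes its quantity from first principles (exhaustive scans, flood
# fill, from-scratch region statistics) so it shares no code path with the
# package implementation it checks.

# ---- contrast split: exhaustive threshold search over distinct values ----
# Between-class-variance (Otsu) contrast objective, computed naively with
# mean() per candidate threshold.
oracle_contrast_split <- function(values, domain = NULL) {
  if (is.null(domain)) domain <- matrix(TRUE, nrow(values), ncol(values))
  v <- values[domain]
  cand <- sort(unique(v))
  best <- list(obj = -Inf, thr = NA_real_)
  for (t in cand) {
    bright <- v >= t
    if (!any(bright) || all(bright)) next
    w <- mean(bright)
    obj <- w * (1 - w) * (mean(v[bright]) - mean(v[!bright]))^2
    if (obj > best$obj) best <- list(obj = obj, thr = t)
  }
  bright_mask <- domain & (values >= best$thr)
  list(threshold = best$thr, objective = best$obj, bright_mask = bright_mask)
}

# Two-component mixture image with a wide empty intensity gap, so the best
# bright/dark partition is unambiguous and expressible by any threshold grid.
make_mixture_image <- function(nr = 16L, nc = 16L, seed = 1L) {
  withr::with_seed(seed, {
    frac <- runif(1, 0.25, 0.75)
    n <- nr * nc
    hi <- rbinom(n, 1, frac) == 1L
    v <- numeric(n)
    v[hi] <- pmin(pmax(rnorm(sum(hi), 0.8, 0.02), 0.72), 0.88)
    v[!hi] <- pmin(pmax(rnorm(sum(!hi), 0.2, 0.02), 0.12), 0.28)
    matrix(v, nr, nc)
  })
}

# ---- flood-fill connected components ------------------------------------
oracle_components <- function(mask, connectivity = 4L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- if (connectivity == 8L)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue) > 0L) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        qi <- p[1] + offs[k, 1]; qj <- p[2] + offs[k, 2]
        if (qi >= 1 && qi <= nr && qj >= 1 && qj <= nc &&
            mask[qi, qj] && lab[qi, qj] == 0L) {
          lab[qi, qj] <- nxt
          queue[[length(queue) + 1L]] <- c(qi, qj)
        }
      }
    }
  }
  list(labels = lab, n = nxt)
}

# ---- crack perimeter: enumerate every exposed pixel edge ----------------
oracle_crack_edges <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  edges <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j]) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      qi <- i + d[1]; qj <- j + d[2]
      if (qi < 1 || qi > nr || qj < 1 || qj > nc || !mask[qi, qj])
        edges <- edges + 1L
    }
  }
  edges
}

# ---- minimum-perimeter enclosing rectangle: 0.5 degree orientation scan --
oracle_min_rect_perimeter <- function(mask, pad = 1) {
  pts <- which(mask, arr.ind = TRUE)
  x <- pts[, 2]; y <- pts[, 1]
  best <- Inf
  for (deg in seq(0, 89.5, by = 0.5)) {
    th <- deg * pi / 180
    u <- x * cos(th) + y * sin(th)
    v <- -x * sin(th) + y * cos(th)
    p <- 2 * ((diff(range(u)) + pad) + (diff(range(v)) + pad))
    best <- min(best, p)
  }
  best
}

# ---- multi-resolution merging: naive greedy mutual-best-fitting ---------
# Same documented cost model, scan order and stopping rule as the package
# engine, but every region statistic (sd, perimeter, bounding box) is
# recomputed from scratch off the label matrix at every cost evaluation.
oracle_mrs <- function(channels, weights, domain, perm, scale,
                       shape_w = 0.2, cmpct_w = 0.5, connectivity = 4L) {
  if (is.matrix(channels)) channels <- list(channels)
  nr <- nrow(channels[[1]]); nc <- ncol(channels[[1]])
  N <- nr * nc
  lab <- matrix(NA_integer_, nr, nc)
  lab[domain] <- which(domain)
  pos <- integer(N); pos[perm] <- seq_along(perm)
  scale2 <- scale * scale

  perim_of <- function(mask) {
    n <- sum(mask)
    h <- if (nc > 1) sum(mask[, -nc, drop = FALSE] & mask[, -1, drop = FALSE])
         else 0L
    v <- if (nr > 1) sum(mask[-nr, , drop = FALSE] & mask[-1, , drop = FALSE])
         else 0L
    4L * n - 2L * (h + v)
  }
  region_cost_part <- function(mask) {
    px <- which(mask)
    n <- length(px)
    sds <- vapply(channels, function(ch) {
      v <- ch[px]; sqrt(max(sum(v * v) / n - (sum(v) / n)^2, 0))
    }, numeric(1))
    rc <- arrayInd(px, c(nr, nc))
    bb <- 2 * ((diff(range(rc[, 1])) + 1) + (diff(range(rc[, 2])) + 1))
    p <- perim_of(mask)
    list(n = n, sds = sds, p = p, bb = bb)
  }
  merge_cost <- function(a, b) {
    ma <- !is.na(lab) & lab == a
    mb <- !is.na(lab) & lab == b
    sa <- region_cost_part(ma); sb <- region_cost_part(mb)
    sm <- region_cost_part(ma | mb)
    col <- sum(weights * (sm$n * sm$sds - sa$n * sa$sds - sb$n * sb$sds))
    if (shape_w == 0) return(col)
    cmp <- sm$p * sqrt(sm$n) - sa$p * sqrt(sa$n) - sb$p * sqrt(sb$n)
    smo <- sm$n * sm$p / sm$bb - sa$n * sa$p / sa$bb - sb$n * sb$p / sb$bb
    (1 - shape_w) * col + shape_w * (cmpct_w * cmp + (1 - cmpct_w) * smo)
  }
  neighbors_of <- function(r) {
    mask <- !is.na(lab) & lab == r
    offs <- if (connectivity == 8L)
      list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
           c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
    else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
    nb <- integer(0)
    idx <- which(mask, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) for (d in offs) {
      qi <- idx[k, 1] + d[1]; qj <- idx[k, 2] + d[2]
      if (qi >= 1 && qi <= nr && qj >= 1 && qj <= nc &&
          !is.na(lab[qi, qj]) && lab[qi, qj] != r)
        nb <- c(nb, lab[qi, qj])
    }
    sort(unique(nb))
  }
  best_neighbor <- function(r) {
    nb <- neighbors_of(r)
    if (length(nb) == 0L) return(NULL)
    costs <- vapply(nb, function(b) merge_cost(r, b), numeric(1))
    k <- which.min(costs)  # ascending ids: first minimum = smallest id
    list(id = nb[k], cost = costs[k])
  }

  repeat {
    changed <- FALSE
    roots <- sort(unique(lab[!is.na(lab)]))
    roots <- roots[order(pos[roots])]
    for (r in roots) {
      if (!any(lab == r, na.rm = TRUE)) next
      b <- best_neighbor(r)
      if (is.null(b) || !(b$cost < scale2)) next
      b2 <- best_neighbor(b$id)
      if (!is.null(b2) && b2$id == r) {
        keep <- min(r, b$id)
        lab[lab == r | lab == b$id] <- keep
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # relabel 1..n by row-major first appearance
  out <- matrix(0L, nr, nc)
  map <- integer(0)
  nxt <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(lab[i, j])) next
    key <- as.character(lab[i, j])
    if (is.na(match(key, names(map)))) {
      nxt <- nxt + 1L
      map[key] <- nxt
    }
    out[i, j] <- map[[key]]
  }
  list(labels = out, n_segments = nxt)
}

# ---- small synthetic scene used across end-to-end tests -----------------
# 21.6 x 32.4 m frame at 0.12 m/pixel: the same intensity model as the
# full-size defaults at a desk-scale problem size.
test_scene_spec <- function(seed, n_bergs = 3L, brash_cov = 0.15,
                            ice_level = NULL, ...) {
  bergs <- list(n = n_bergs, mean_area_m2 = 20, sd_area_m2 = 8,
                area_min_m2 = 8, area_max_m2 = 45)
  brash <- list(coverage = brash_cov)
  if (!is.null(ice_level)) {
    bergs$intensity <- 0.15 + ice_level
    brash$intensity <- 0.15 + 0.8 * ice_level
  }
  synthetic_scene_spec(height_px = 180L, width_px = 270L,
                       pixel_size_m = 0.12, brash = brash,
                       icebergs = bergs, seed = seed, ...)
}
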