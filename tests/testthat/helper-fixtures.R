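# Fixture builders and independent brute-force oracles shared by the suite.

# wrap a logical matrix as a single seed mask
as_seed_mask <- function(m, dpi = 400) {
  parts <- label_particles(m, min_area_px = 1, exclude_border = FALSE, dpi = dpi)
  stopifnot(length(parts) == 1)
  parts[[1]]
}

disk_mask <- function(r, pad = 6) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  g <- expand.grid(row = 1:n, col = 1:n)
  m <- matrix(FALSE, n, n)
  m[as.matrix(g[sqrt((g$row - ctr)^2 + (g$col - ctr)^2) <= r, ])] <- TRUE
  m
}

rect_mask <- function(h, w, pad = 3) {
  m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  m[(pad + 1):(pad + h), (pad + 1):(pad + w)] <- TRUE
  m
}

# small random seed-shaped mask (<= 60 x 60) via the outline generator
random_blob_mask <- function(dpi = 170) {
  p <- shape_params("BLOB", scale_mm = stats::runif(1, 4, 7),
                    aspect = stats::runif(1, 0.45, 0.9),
                    stalk_amplitude = stats::runif(1, 0, 0.15),
                    coeff_sd = stats::runif(1, 0, 0.04))
  o <- sample_outline(p)
  sc <- render_scene(list(o), dpi = dpi, margin_px = 4)
  parts <- label_particles(binarize(sc$image), dpi = dpi)
  stopifnot(length(parts) == 1)
  parts[[1]]
}

rotate_mask_90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]

# --- independent geometry oracles (no shared shortcuts) ---------------------

# Jarvis march convex hull (gift wrapping), O(n h)
hull_jarvis <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n <= 2) return(pts)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (length(hull) == 1) setdiff(seq_len(n), cur) else seq_len(n)[-cur]
    nxt <- cand[1]
    for (j in cand[-1]) {
      cr <- (pts[nxt, 1] - pts[cur, 1]) * (pts[j, 2] - pts[cur, 2]) -
        (pts[nxt, 2] - pts[cur, 2]) * (pts[j, 1] - pts[cur, 1])
      d_nxt <- sum((pts[nxt, ] - pts[cur, ])^2)
      d_j <- sum((pts[j, ] - pts[cur, ])^2)
      if (cr > 1e-12 || (abs(cr) <= 1e-12 && d_j > d_nxt)) nxt <- j
    }
    cur <- nxt
    if (cur == start) break
  }
  pts[hull, , drop = FALSE]
}

poly_area_bf <- function(xy) {
  n <- nrow(xy)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + xy[i, 1] * xy[j, 2] - xy[j, 1] * xy[i, 2]
  }
  unname(abs(s) / 2)
}

poly_perim_bf <- function(xy) {
  n <- nrow(xy)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + sqrt(sum((xy[i, ] - xy[j, ])^2))
  }
  unname(s)
}

# exhaustive base-quantity oracle for one seed mask
morpho_oracle <- function(seed, contour) {
  pts <- contour$points
  n <- nrow(pts)
  # Feret: all pairs over ALL boundary points; ties canonicalised to the
  # lexicographically smallest endpoint pair (endpoints sorted within pair)
  bmax <- -1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sum((pts[i, ] - pts[j, ])^2)
    if (d > bmax) bmax <- d
  }
  cand <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sum((pts[i, ] - pts[j, ])^2)
    if (d >= bmax * (1 - 1e-12)) {
      a <- pts[i, ]; b <- pts[j, ]
      pr <- if (a[1] < b[1] || (a[1] == b[1] && a[2] <= b[2])) c(a, b) else c(b, a)
      cand <- rbind(cand, pr)
    }
  }
  best <- cand[order(cand[, 1], cand[, 2], cand[, 3], cand[, 4])[1], ]
  feret <- sqrt(bmax)
  u <- (best[3:4] - best[1:2]) / feret
  proj <- pts %*% c(-u[2], u[1])
  breadth <- unname(max(proj) - min(proj))
  # centroid straight from the filled pixels
  idx <- which(seed$mask)
  fr <- (idx - 1) %% nrow(seed$mask)
  fc <- (idx - 1) %/% nrow(seed$mask)
  ctr <- c(mean(fc) + seed$offset[["col"]], mean(fr) + seed$offset[["row"]])
  dctr <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  hull <- hull_jarvis(pts)
  lapply(list(Pixels = length(idx),
              Area = poly_area_bf(pts),
              Feret = feret, Breadth = breadth,
              MinR = min(dctr), MaxR = max(dctr),
              CHull = poly_perim_bf(hull), CArea = poly_area_bf(hull),
              MBCRadius = mbc_oracle(hull)), unname)
}

# O(n^3) minimal-bounding-circle oracle: try all pair-diameter and
# three-point circumscribed circles, keep the smallest that covers all
mbc_oracle <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  covers <- function(ctr, r) all(sqrt((pts[, 1] - ctr[1])^2 +
                                        (pts[, 2] - ctr[2])^2) <= r + 1e-9)
  best <- Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ctr <- (pts[i, ] + pts[j, ]) / 2
    r <- sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2
    if (r < best && covers(ctr, r)) best <- r
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      p <- pts[i, ]; q <- pts[j, ]; s <- pts[k, ]
      d <- 2 * (p[1] * (q[2] - s[2]) + q[1] * (s[2] - p[2]) + s[1] * (p[2] - q[2]))
      if (abs(d) < 1e-12) next
      ux <- (sum(p^2) * (q[2] - s[2]) + sum(q^2) * (s[2] - p[2]) +
               sum(s^2) * (p[2] - q[2])) / d
      uy <- (sum(p^2) * (s[1] - q[1]) + sum(q^2) * (p[1] - s[1]) +
               sum(s^2) * (q[1] - p[1])) / d
      r <- sqrt(sum((p - c(ux, uy))^2))
      if (r < best && covers(c(ux, uy), r)) best <- r
    }
  }
  best
}

# Gaussian feature-table fixture: two groups, `p` feature columns of which
# `n_signal` differ in mean by `delta` (sd 1); columns named like the real
# 103-variable block when p == 103
gaussian_feature_table <- function(n_per_group = 30, p = 103, delta = 6,
                                   n_signal = 3,
                                   groups = c("WILD", "CULTIVATED")) {
  n <- 2 * n_per_group
  X <- matrix(stats::rnorm(n * p), n, p)
  if (n_signal > 0) {
    shift <- matrix(0, n, n_signal)
    shift[seq_len(n_per_group), ] <- delta
    X[, seq_len(n_signal)] <- X[, seq_len(n_signal)] + shift
  }
  colnames(X) <- if (p == 103) feature_names() else sprintf("V%03d", seq_len(p))
  d <- tibble::as_tibble(X)
  d$class_label <- rep(groups, each = n_per_group)
  d
}

# fully nested leave-one-out accuracy (selection redone per fold); folds in
# which no variable clears the entry threshold fall back to the prior-only
# classifier (first group in label order)
nested_loocv_accuracy <- function(feats) {
  cv <- suppressWarnings(loocv(feats, character(0), reselect = TRUE))
  mean(cv$correct)
}

# tiny rendered two-class dataset (kept small: unit tests only)
tiny_dataset <- function(dir, n = 6, seed = 301, dpi = 200, separation = 1,
                         unknown = 0, charred = FALSE) {
  lots <- list(
    list(code = "W", class = "WILD", n = n, charred = charred),
    list(code = "C", class = "CULTIVATED", n = n, charred = charred))
  if (unknown > 0)
    lots <- c(lots, list(list(code = "U", class = "WILD", n = unknown,
                              charred = charred, group = "UNKNOWN")))
  make_seed_dataset(
    list(rng_seed = seed, dpi = dpi, separation = separation, lots = lots),
    dir)
}
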