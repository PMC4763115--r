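#' The 26 particle shape descriptor names
#'
#' Column names, in frozen order, of the morphometric block of the feature
#' table: size measures in pixel units plus classical dimensionless shape
#' ratios (circularity, roundness, solidity, sphericity, rectangularity,
#' ...).
#' @return character vector of length 26.
#' @export
morpho_names <- function() {
  c("Perim", "Area", "Pixels", "MinR", "MaxR", "Feret", "Breadth", "CHull",
    "CArea", "MBCRadius", "AspRatio", "Circ", "Roundness", "ArEquivD",
    "PerEquivD", "EquivEllAr", "Compactness", "Solidity", "Concavity",
    "Convexity", "Shape", "RFactor", "ModRatio", "Sphericity", "ArBBox",
    "Rectang")
}

#' Measure the 26 shape descriptors of a seed silhouette
#'
#' Computes the classical particle descriptors from a silhouette mask and
#' its chain-coded boundary. Base quantities: `Pixels` is the foreground
#' count; `Area` the shoelace area of the boundary-centre polygon; `Perim`
#' the Freeman chain length (1 per axial step, sqrt(2) per diagonal);
#' `CHull`/`CArea` the perimeter and area of the convex hull of boundary
#' pixel centres; `Feret` the largest distance between hull vertices;
#' `Breadth` the largest hull extent perpendicular to the Feret axis;
#' `MinR`/`MaxR` the smallest/largest centroid-to-boundary distance (the
#' centroid is the silhouette's centre of mass); `MBCRadius` the radius of
#' the exact minimal enclosing circle of the hull vertices. The 16 derived
#' ratios follow the standard definitions (see the package vignette for the
#' full table).
#'
#' `PerEquivD` is `Perim/pi` by default. Set `strict_per_equiv_d = TRUE`
#' for the variant `Area/pi` that some legacy feature lists print
#' (dimensionally an area rather than a diameter; kept only for
#' compatibility).
#'
#' @param seed a `seed_mask` from [label_particles()].
#' @param contour the matching `seed_contour` from [trace_boundary()];
#'   computed if omitted.
#' @param strict_per_equiv_d use the legacy `Area/pi` form of `PerEquivD`.
#' @return a 1-row tibble with the 26 columns of [morpho_names()], in pixel
#'   units; convert with [to_physical()].
#' @export
measure_seed <- function(seed, contour = NULL, strict_per_equiv_d = FALSE) {
  stopifnot(inherits(seed, "seed_mask"))
  if (is.null(contour)) contour <- trace_boundary(seed)
  pts <- contour$points
  if (nrow(unique(pts)) < 3) abort("degenerate contour: fewer than 3 distinct points")

  Perim <- sum(chain_step_lengths(contour$chain))
  Area <- abs(polygon_signed_area(pts))
  Pixels <- seed$area_px

  hull <- pts[rev(grDevices::chull(pts[, 1], pts[, 2])), , drop = FALSE]
  CHull <- polygon_perimeter(hull)
  CArea <- abs(polygon_signed_area(hull))

  fr <- feret_breadth(hull)
  Feret <- fr$feret; Breadth <- fr$breadth

  ctr <- seed$centroid
  dctr <- sqrt((pts[, 1] - ctr[["x"]])^2 + (pts[, 2] - ctr[["y"]])^2)
  MinR <- min(dctr); MaxR <- max(dctr)

  MBCRadius <- min_enclosing_circle(hull)$radius

  ArEquivD <- sqrt(4 * Area / pi)
  tibble(
    Perim = Perim, Area = Area, Pixels = Pixels, MinR = MinR, MaxR = MaxR,
    Feret = Feret, Breadth = Breadth, CHull = CHull, CArea = CArea,
    MBCRadius = MBCRadius,
    AspRatio = Feret / Breadth,
    Circ = 4 * pi * Area / Perim^2,
    Roundness = 4 * Area / (pi * Feret^2),
    ArEquivD = ArEquivD,
    PerEquivD = if (strict_per_equiv_d) Area / pi else Perim / pi,
    EquivEllAr = pi * Feret * Breadth / 4,
    Compactness = ArEquivD / Feret,
    Solidity = Area / CArea,
    Concavity = CArea - Area,
    Convexity = CHull / Perim,
    Shape = Perim^2 / Area,
    RFactor = CHull / (Feret * pi),
    ModRatio = 2 * MinR / Feret,
    Sphericity = MinR / MaxR,
    ArBBox = Feret * Breadth,
    Rectang = Area / (Feret * Breadth))
}

# Feret diameter (max pairwise distance among hull vertices) and the breadth
# perpendicular to its axis. Integer pixel coordinates produce exact distance
# ties, so the achieving pair is canonicalised: lexicographically smallest
# (x1, y1, x2, y2) with each pair's endpoints sorted.
feret_breadth <- function(hull) {
  n <- nrow(hull)
  if (n == 1) return(list(feret = 0, breadth = 0))
  d2 <- as.matrix(stats::dist(hull))^2
  m <- max(d2)
  ties <- which(d2 >= m * (1 - 1e-12) & upper.tri(d2), arr.ind = TRUE)
  pairs <- t(apply(ties, 1, function(ij) {
    a <- hull[ij[1], ]; b <- hull[ij[2], ]
    if (a[1] < b[1] || (a[1] == b[1] && a[2] <= b[2])) c(a, b) else c(b, a)
  }))
  best <- pairs[order(pairs[, 1], pairs[, 2], pairs[, 3], pairs[, 4])[1], ]
  p1 <- best[1:2]; p2 <- best[3:4]
  feret <- sqrt(sum((p2 - p1)^2))
  u <- (p2 - p1) / feret
  perp <- c(-u[2], u[1])
  proj <- hull %*% perp
  list(feret = feret, breadth = unname(max(proj) - min(proj)))
}

#' Minimal enclosing circle (Welzl's algorithm)
#'
#' Exact smallest circle covering a point set, by the randomized-incremental
#' construction run in a fixed deterministic order.
#'
#' @param pts n x 2 matrix of points.
#' @return list with `center` (length-2) and `radius`.
#' @export
min_enclosing_circle <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  tol <- 1e-10
  inside <- function(circ, p) {
    sqrt(sum((p - circ$center)^2)) <= circ$radius * (1 + 1e-12) + tol
  }
  circ2 <- function(p, q) {
    list(center = (p + q) / 2, radius = sqrt(sum((p - q)^2)) / 2)
  }
  circ3 <- function(p, q, r) {
    ax <- p[1]; ay <- p[2]; bx <- q[1]; by <- q[2]; cx <- r[1]; cy <- r[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-14) {
      # collinear: take the extreme pair
      cands <- list(circ2(p, q), circ2(p, r), circ2(q, r))
      cands[[which.max(vapply(cands, `[[`, numeric(1), "radius"))]]
    } else {
      ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
               (cx^2 + cy^2) * (ay - by)) / d
      uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
               (cx^2 + cy^2) * (bx - ax)) / d
      ctr <- c(ux, uy)
      list(center = ctr, radius = sqrt(sum((p - ctr)^2)))
    }
  }
  circle_from <- function(support) {
    k <- nrow(support)
    if (k == 0) return(list(center = c(0, 0), radius = 0))
    if (k == 1) return(list(center = support[1, ], radius = 0))
    if (k == 2) return(circ2(support[1, ], support[2, ]))
    circ3(support[1, ], support[2, ], support[3, ])
  }
  welzl <- function(P, R) {
    if (nrow(P) == 0 || nrow(R) == 3) return(circle_from(R))
    p <- P[nrow(P), , drop = FALSE]
    circ <- welzl(P[-nrow(P), , drop = FALSE], R)
    if (inside(circ, p[1, ])) return(circ)
    welzl(P[-nrow(P), , drop = FALSE], rbind(R, p))
  }
  welzl(pts, pts[0, , drop = FALSE])
}

#' Convert descriptors from pixel units to millimetres
#'
#' Lengths scale by `pixel_size_mm`, areas by its square; `Pixels` and the
#' dimensionless ratios are unchanged. Classification runs in pixel units
#' (discriminant analysis is affine-invariant); millimetre conversion is for
#' presentation.
#'
#' @param features tibble of [measure_seed()] rows (extra columns pass
#'   through untouched).
#' @param pixel_size_mm length of one pixel in mm (`25.4/dpi`).
#' @return the tibble with measurement columns rescaled.
#' @export
to_physical <- function(features, pixel_size_mm) {
  if (!is.numeric(pixel_size_mm) || pixel_size_mm <= 0)
    abort("pixel_size_mm must be a positive number")
  len <- c("Perim", "MinR", "MaxR", "Feret", "Breadth", "CHull", "MBCRadius",
           "ArEquivD", "PerEquivD")
  area <- c("Area", "CArea", "Concavity", "EquivEllAr", "ArBBox")
  features |>
    dplyr::mutate(dplyr::across(dplyr::any_of(len), ~ .x * pixel_size_mm),
                  dplyr::across(dplyr::any_of(area), ~ .x * pixel_size_mm^2))
}
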