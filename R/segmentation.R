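#' Binarize a grayscale seed scan
#'
#' Thresholds an 8-bit grayscale image into a foreground mask. Foreground is
#' the dark phase (seeds on a light scanner background) unless `invert` is
#' set. The default threshold is Otsu's method (maximising between-class
#' variance of the 256-bin histogram); `method = "fixed"` uses
#' `manual_threshold`.
#'
#' @param image integer matrix of gray values 0-255.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param manual_threshold threshold in 0-255, required for
#'   `method = "fixed"`; pixels `<= threshold` are foreground (or `>` when
#'   inverted).
#' @param invert if `TRUE`, the light phase is foreground.
#' @return logical matrix, `TRUE` = foreground.
#' @export
binarize <- function(image, method = c("otsu", "fixed"),
                     manual_threshold = NULL, invert = FALSE) {
  method <- match.arg(method)
  if (method == "fixed" && is.null(manual_threshold))
    abort("method = \"fixed\" requires manual_threshold")
  v <- as.vector(image)
  if (length(unique(v)) == 1) {
    warn("uniform image: no foreground found")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  thr <- if (method == "otsu") otsu_threshold(v) else manual_threshold
  fg <- if (invert) image > thr else image <= thr
  fg
}

# Otsu threshold on integer gray values 0..255: returns the cut t such that
# classes are {<= t} and {> t}, maximising between-class variance (first
# maximum on ties).
otsu_threshold <- function(v) {
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  which.max(sb) - 1L
}

# 8-connected component labelling on a logical matrix (frontier BFS on a
# zero-padded copy). Returns an integer matrix of labels, 0 = background.
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  nrp <- nr + 2L
  maskp <- matrix(FALSE, nrp, nc + 2L)
  maskp[2:(nr + 1), 2:(nc + 1)] <- mask
  offs <- c(-1L, 1L, -nrp - 1L, -nrp, -nrp + 1L, nrp - 1L, nrp, nrp + 1L)
  lab <- integer(length(maskp))
  comp <- 0L
  for (s in which(as.vector(maskp))) {
    if (lab[s]) next
    comp <- comp + 1L
    lab[s] <- comp
    frontier <- s
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, offs, `+`)))
      nb <- nb[maskp[nb] & lab[nb] == 0L]
      lab[nb] <- comp
      frontier <- nb
    }
  }
  matrix(lab, nrp, nc + 2L)[2:(nr + 1), 2:(nc + 1)]
}

# Fill interior holes: background not reachable 4-connectedly from the
# border becomes foreground.
fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  nrp <- nr + 2L
  bgp <- matrix(TRUE, nrp, nc + 2L)
  bgp[2:(nr + 1), 2:(nc + 1)] <- !mask
  offs <- c(-1L, 1L, -nrp, nrp)
  reach <- logical(length(bgp))
  reach[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nb <- unique(as.vector(outer(frontier, offs, `+`)))
    nb <- nb[nb >= 1 & nb <= length(bgp)]
    nb <- nb[bgp[nb] & !reach[nb]]
    reach[nb] <- TRUE
    frontier <- nb
  }
  reach <- matrix(reach, nrp, nc + 2L)[2:(nr + 1), 2:(nc + 1)]
  mask | !reach
}

#' Extract individual seed silhouettes from a binary mask
#'
#' Finds 8-connected foreground components, drops specks below `min_area_px`
#' and (optionally) components touching the image border, fills interior
#' holes (charred seeds often scan with bright specks), and returns the
#' particles in reading order (top-left corner of the bounding box, row-major).
#'
#' @param mask logical matrix from [binarize()].
#' @param min_area_px minimum particle area in pixels (after hole filling).
#' @param exclude_border drop components touching the image border.
#' @param dpi raster resolution, recorded as `pixel_size_mm = 25.4/dpi`.
#' @return list of `seed_mask` objects: `mask` (cropped logical matrix,
#'   holes filled), `offset` (0-based row/col of the crop origin in the
#'   source image), `centroid` (x, y in 0-based pixel-centre coordinates of
#'   the source image), `area_px`, `pixel_size_mm`.
#' @export
label_particles <- function(mask, min_area_px = 50, exclude_border = TRUE,
                            dpi = 400) {
  lab <- label_components8(mask)
  ncomp <- max(lab)
  if (ncomp == 0) return(list())
  seeds <- list()
  bbox_key <- NULL
  for (k in seq_len(ncomp)) {
    idx <- which(lab == k)
    rr <- (idx - 1L) %% nrow(mask) + 1L
    cc <- (idx - 1L) %/% nrow(mask) + 1L
    r0 <- min(rr); r1 <- max(rr); c0 <- min(cc); c1 <- max(cc)
    if (exclude_border &&
        (r0 == 1 || c0 == 1 || r1 == nrow(mask) || c1 == ncol(mask))) next
    crop <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    crop[cbind(rr - r0 + 1L, cc - c0 + 1L)] <- TRUE
    crop <- fill_holes(crop)
    area <- sum(crop)
    if (area < min_area_px) next
    fidx <- which(crop)
    fr <- (fidx - 1L) %% nrow(crop)
    fc <- (fidx - 1L) %/% nrow(crop)
    seeds[[length(seeds) + 1L]] <- structure(
      list(mask = crop,
           offset = c(row = r0 - 1L, col = c0 - 1L),
           centroid = c(x = mean(fc) + c0 - 1L, y = mean(fr) + r0 - 1L),
           area_px = area,
           pixel_size_mm = 25.4 / dpi),
      class = "seed_mask")
    bbox_key <- rbind(bbox_key, c(r0, c0))
  }
  if (!length(seeds)) return(list())
  ord <- order(bbox_key[, 1], bbox_key[, 2])
  seeds[ord]
}

#' Trace the chain-coded boundary of a seed silhouette
#'
#' Moore boundary tracing over boundary pixel centres, starting from the
#' topmost-then-leftmost foreground pixel, with orientation forced
#' counter-clockwise (positive signed area in y-up axes). The Freeman chain
#' encodes each step between consecutive boundary pixels as one of 8
#' directions (0 = +x, counter-clockwise in Cartesian axes); axial steps
#' have length 1, diagonal steps sqrt(2), and their sum is the perimeter
#' convention used by the shape descriptors.
#'
#' @param seed a `seed_mask` from [label_particles()].
#' @return an object of class `seed_contour`: `points` (n x 2 matrix of
#'   boundary pixel centres, 0-based source-image x/y, y down), `chain`
#'   (integer Freeman codes, `chain[i]` is the step from point i to point
#'   i + 1, wrapping), `start_index` (always 1: the topmost-leftmost pixel).
#' @export
trace_boundary <- function(seed) {
  stopifnot(inherits(seed, "seed_mask"))
  if (seed$area_px < 4) abort("degenerate particle: area_px < 4")
  m <- seed$mask
  nr <- nrow(m); nc <- ncol(m)
  mp <- matrix(FALSE, nr + 2L, nc + 2L)
  mp[2:(nr + 1), 2:(nc + 1)] <- m
  # Moore neighbourhood in clockwise screen order starting at W (y down)
  dirs <- cbind(dr = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
                dc = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L))
  dir_index <- function(dr, dc) which(dirs[, 1] == dr & dirs[, 2] == dc)

  # scan clockwise around `cur` starting just past the backtrack pixel `b`;
  # returns the first foreground neighbour, the last background pixel
  # scanned before it (the new backtrack), and the step direction taken
  find_next <- function(cur, b) {
    d0 <- dir_index(b[1] - cur[1], b[2] - cur[2])
    for (s in 1:8) {
      di <- ((d0 - 1L + s) %% 8L) + 1L
      cand <- cur + dirs[di, ]
      if (mp[cand[1], cand[2]]) return(list(nb = cand, b = b, di = di))
      b <- cand
    }
    NULL
  }

  fg <- which(m)
  rr <- (fg - 1L) %% nr + 1L; cc <- (fg - 1L) %/% nr + 1L
  top <- which(rr == min(rr)); sidx <- top[which.min(cc[top])]
  start <- c(rr[sidx] + 1L, cc[sidx] + 1L)  # padded coords
  b0 <- start + c(0L, -1L)  # west neighbour is background at this start

  first <- find_next(start, b0)
  pts <- list(start)
  cur <- first$nb; b <- first$b
  while (!(all(cur == start))) {
    pts[[length(pts) + 1L]] <- cur
    stp <- find_next(cur, b)
    cur <- stp$nb; b <- stp$b
    if (length(pts) > 4L * seed$area_px + 8L)
      abort("boundary tracing failed to terminate")
  }
  # Jacob's criterion: keep going until re-entering the start pixel would
  # repeat the initial step; intermediate returns to the start pixel (one
  # pixel wide necks) continue the walk
  repeat {
    stp <- find_next(cur, b)
    if (stp$di == first$di) break
    pts[[length(pts) + 1L]] <- cur
    cur <- stp$nb; b <- stp$b
    while (!(all(cur == start))) {
      pts[[length(pts) + 1L]] <- cur
      stp <- find_next(cur, b)
      cur <- stp$nb; b <- stp$b
      if (length(pts) > 4L * seed$area_px + 8L)
        abort("boundary tracing failed to terminate")
    }
  }
  p <- do.call(rbind, pts)
  # to source-image 0-based pixel-centre coordinates
  x <- p[, 2] - 2L + seed$offset[["col"]]
  y <- p[, 1] - 2L + seed$offset[["row"]]
  pts_xy <- cbind(x = as.numeric(x), y = as.numeric(y))
  pts_xy <- unique_consecutive(pts_xy)
  if (polygon_signed_area(cbind(pts_xy[, 1], -pts_xy[, 2])) < 0) {
    n <- nrow(pts_xy)
    pts_xy <- pts_xy[c(1L, n:2L), , drop = FALSE]
  }
  structure(list(points = pts_xy, chain = chain_codes(pts_xy), start_index = 1L),
            class = "seed_contour")
}

unique_consecutive <- function(xy) {
  n <- nrow(xy)
  if (n < 2) return(xy)
  dup <- c(FALSE, rowSums(abs(xy[-1, , drop = FALSE] - xy[-n, , drop = FALSE])) == 0)
  xy <- xy[!dup, , drop = FALSE]
  n <- nrow(xy)
  if (n > 1 && all(xy[1, ] == xy[n, ])) xy <- xy[-n, , drop = FALSE]
  xy
}

# Freeman codes for steps between consecutive points (closing step last).
# Code k corresponds to angle k * 45 degrees in Cartesian (y-up) axes.
chain_codes <- function(pts) {
  n <- nrow(pts)
  nxt <- c(2:n, 1)
  dx <- pts[nxt, 1] - pts[, 1]
  dy <- -(pts[nxt, 2] - pts[, 2])  # y-down storage -> Cartesian
  code <- integer(n)
  lut <- matrix(c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 7L), nrow = 8)
  ang <- atan2(dy, dx)
  k <- round(ang / (pi / 4)) %% 8
  as.integer(k)
}

chain_step_lengths <- function(chain) {
  ifelse(chain %% 2 == 0, 1, sqrt(2))
}

#' @export
print.seed_contour <- function(x, ...) {
  cat(sprintf("<seed_contour> %d boundary points, chain length %.2f px\n",
              nrow(x$points), sum(chain_step_lengths(x$chain))))
  invisible(x)
}

#' @export
print.seed_mask <- function(x, ...) {
  cat(sprintf("<seed_mask> %d px at offset (%d, %d), %.4f mm/px\n",
              x$area_px, x$offset[["row"]], x$offset[["col"]], x$pixel_size_mm))
  invisible(x)
}
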