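#' Elliptic Fourier decomposition of a closed contour
#'
#' Computes elliptic Fourier coefficients of a closed outline by the exact
#' piecewise-linear closed form: the x and y increments along the contour are
#' expanded separately as Fourier series in the cumulative arc length, so the
#' coefficients are exact for the polygonal contour (no FFT approximation).
#' The first harmonic is the best-fitting ellipse of the outline; each
#' harmonic `n` contributes a coefficient quadruple (a_n, b_n, c_n, d_n).
#'
#' Coordinates are assumed Cartesian (y up). Contours traced from raster
#' images (row index increasing downwards) must be converted first; the
#' higher-level extractors in this package do so automatically.
#'
#' @param xy closed polygon as an n x 2 matrix of (x, y) vertices, the closing
#'   edge implicit; or a `seed_contour` object from [trace_boundary()].
#' @param n_harmonics number of harmonics N (>= 1); at most `floor(n/2)`.
#' @param t optional strictly increasing parameter values at the vertices
#'   (length n, starting at 0). By default the cumulative arc length is used,
#'   which is the convention for chain-coded contours. Supplying the curve's
#'   own parameter makes the decomposition exact for curves that are finite
#'   Fourier series in that parameter (e.g. an ellipse).
#' @return An object of class `efd` with elements `A0`, `C0` (centroid
#'   terms), `coeffs` (N x 4 matrix with columns `a`, `b`, `c`, `d`), `T`
#'   (contour length) and `n_harmonics`.
#' @references Kuhl, F. P. and Giardina, C. R. (1982) Elliptic Fourier
#'   features of a closed contour. Computer Graphics and Image Processing 18.
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 200)[-200]
#' ell <- cbind(2 * cos(th), sin(th))
#' ef <- compute_efd(ell, 4)
#' ef$coeffs[1, ] # ~ (2, 0, 0, 1)
compute_efd <- function(xy, n_harmonics = 20, t = NULL) {
  xy <- contour_points_cartesian(xy)
  n <- nrow(xy)
  if (n < 3) abort("contour must have at least 3 points")
  if (n_harmonics < 1) abort("n_harmonics must be >= 1")
  if (n_harmonics > floor(n / 2)) {
    abort(sprintf("contour with %d points supports at most %d harmonics",
                  n, floor(n / 2)))
  }
  # drop an explicitly repeated closing vertex
  if (all(xy[1, ] == xy[n, ])) {
    xy <- xy[-n, , drop = FALSE]
    if (!is.null(t)) t <- t[-n]
    n <- n - 1
  }

  nxt <- c(2:n, 1)
  dx <- xy[nxt, 1] - xy[, 1]
  dy <- xy[nxt, 2] - xy[, 2]
  if (is.null(t)) {
    dt <- sqrt(dx^2 + dy^2)
  } else {
    if (length(t) != n + 1 && length(t) != n)
      abort("t must give one parameter value per vertex (optionally plus the period)")
    period <- if (length(t) == n + 1) t[n + 1] else t[n] + (t[n] - t[n - 1])
    dt <- diff(c(t[seq_len(n)], period))
    if (any(dt <= 0)) abort("t must be strictly increasing")
  }
  keep <- dt > 0
  dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  tp <- cumsum(dt)
  T <- tp[length(tp)]
  tm <- c(0, tp[-length(tp)])

  nh <- seq_len(n_harmonics)
  # outer products: segments x harmonics
  ang_p <- outer(tp, nh) * (2 * pi / T)
  ang_m <- outer(tm, nh) * (2 * pi / T)
  dcos <- cos(ang_p) - cos(ang_m)
  dsin <- sin(ang_p) - sin(ang_m)
  k <- T / (2 * nh^2 * pi^2)
  a <- k * colSums((dx / dt) * dcos)
  b <- k * colSums((dx / dt) * dsin)
  cc <- k * colSums((dy / dt) * dcos)
  d <- k * colSums((dy / dt) * dsin)

  # DC (centroid) terms
  xi <- cumsum(dx) - dx - (dx / dt) * tm
  delta <- cumsum(dy) - dy - (dy / dt) * tm
  A0 <- xy[1, 1] + sum((dx / (2 * dt)) * (tp^2 - tm^2) + xi * (tp - tm)) / T
  C0 <- xy[1, 2] + sum((dy / (2 * dt)) * (tp^2 - tm^2) + delta * (tp - tm)) / T

  structure(
    list(A0 = A0, C0 = C0,
         coeffs = cbind(a = a, b = b, c = cc, d = d),
         T = T, n_harmonics = n_harmonics),
    class = "efd")
}

#' Normalize elliptic Fourier coefficients by the first-harmonic ellipse
#'
#' Removes start-point phase, rotation and size using the first harmonic:
#' the coefficient quadruples are phase-shifted so the parameter origin lies
#' on the semi-major axis of the first-harmonic ellipse, rotated so that axis
#' lies along x, and divided by the semi-major axis magnitude. After
#' normalization `a1 = 1` and `b1 = c1 = 0` exactly, leaving `4N - 3` free
#' coefficients (77 at N = 20): `d1` and the full quadruples of harmonics
#' 2..N. The remaining two-fold ambiguity (a simultaneous half-period start
#' shift and 180-degree rotation) is resolved by requiring `a2 >= 0`.
#' Reflection is deliberately not normalized away: mirror-image outlines
#' (e.g. the two scanned sides of a seed) keep distinct coefficients.
#'
#' @param raw an `efd` object from [compute_efd()].
#' @return An object of class `efd_norm`: `coeffs` (normalized N x 4 matrix),
#'   `free` (named numeric vector of the 4N - 3 free coefficients, order
#'   `d1, a2, b2, c2, d2, ...`), and the removed transform `E` (semi-major
#'   axis, pixels/mm), `theta` (start-phase shift, rad), `psi` (rotation,
#'   rad).
#' @export
normalize_efd <- function(raw) {
  stopifnot(inherits(raw, "efd"))
  cf <- raw$coeffs
  a1 <- cf[1, 1]; b1 <- cf[1, 2]; c1 <- cf[1, 3]; d1 <- cf[1, 4]

  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 + c1^2 - b1^2 - d1^2)
  # candidate phase shifts a quarter period apart; keep the semi-major one
  cand <- c(theta, theta + pi / 2)
  E2 <- vapply(cand, function(th) {
    (a1 * cos(th) + b1 * sin(th))^2 + (c1 * cos(th) + d1 * sin(th))^2
  }, numeric(1))
  theta <- cand[which.max(E2)]
  astar <- a1 * cos(theta) + b1 * sin(theta)
  cstar <- c1 * cos(theta) + d1 * sin(theta)
  E <- sqrt(astar^2 + cstar^2)
  if (E < 1e-12) abort("degenerate first harmonic: cannot normalize")
  psi <- atan2(cstar, astar)

  rot <- matrix(c(cos(psi), sin(psi), -sin(psi), cos(psi)), 2, 2, byrow = TRUE)
  norm_cf <- cf
  for (n in seq_len(nrow(cf))) {
    m <- matrix(cf[n, ], 2, 2, byrow = TRUE) # [a b; c d]
    s <- matrix(c(cos(n * theta), -sin(n * theta),
                  sin(n * theta),  cos(n * theta)), 2, 2, byrow = TRUE)
    norm_cf[n, ] <- as.vector(t(rot %*% m %*% s)) / E
  }

  # branch fix: half-period start shift + pi rotation flips the sign of the
  # even harmonics only; pick the branch with a2 >= 0
  if (nrow(norm_cf) >= 2 && norm_cf[2, 1] < 0) {
    even <- seq(2, nrow(norm_cf), by = 2)
    norm_cf[even, ] <- -norm_cf[even, ]
    theta <- theta + pi
    psi <- psi + pi
  }
  # exact zeros for the fixed coefficients
  norm_cf[1, 1] <- 1; norm_cf[1, 2] <- 0; norm_cf[1, 3] <- 0

  structure(
    list(coeffs = norm_cf, free = efd_free_vector(norm_cf),
         E = E, theta = theta, psi = psi,
         n_harmonics = raw$n_harmonics),
    class = "efd_norm")
}

#' Names of the free normalized coefficients
#'
#' @param n_harmonics harmonic count N.
#' @return character vector of length `4 * n_harmonics - 3`:
#'   `d1, a2, b2, c2, d2, ..., dN`.
#' @export
efd_names <- function(n_harmonics = 20) {
  if (n_harmonics < 1) abort("n_harmonics must be >= 1")
  nm <- "d1"
  if (n_harmonics >= 2) {
    hs <- 2:n_harmonics
    nm <- c(nm, paste0(rep(c("a", "b", "c", "d"), times = length(hs)),
                       rep(hs, each = 4)))
  }
  nm
}

efd_free_vector <- function(norm_cf) {
  n <- nrow(norm_cf)
  v <- norm_cf[1, 4]
  if (n >= 2) v <- c(v, as.vector(t(norm_cf[2:n, , drop = FALSE])))
  setNames(v, efd_names(n))
}

# Rebuild an N x 4 coefficient matrix from a free vector (a1=1, b1=c1=0).
efd_coeffs_from_free <- function(free) {
  stopifnot(length(free) %% 4 == 1)
  n <- (length(free) + 3) / 4
  cf <- matrix(0, n, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  cf[1, ] <- c(1, 0, 0, free[1])
  if (n >= 2) cf[2:n, ] <- matrix(free[-1], n - 1, 4, byrow = TRUE)
  cf
}

#' Evaluate an elliptic Fourier series as a polygon
#'
#' Inverse transform: reconstructs the outline at `n_points` uniformly spaced
#' parameter values. Accepts a raw or normalized coefficient object, or a
#' plain N x 4 coefficient matrix.
#'
#' @param efd an `efd` or `efd_norm` object, or an N x 4 matrix of
#'   coefficient quadruples.
#' @param n_points number of polygon vertices (>= 8).
#' @return an `n_points` x 2 matrix of (x, y) vertices (closing edge
#'   implicit).
#' @export
reconstruct_efd <- function(efd, n_points = 256) {
  if (n_points < 8) abort("n_points must be >= 8")
  if (inherits(efd, c("efd", "efd_norm"))) {
    cf <- efd$coeffs
    A0 <- efd$A0 %||% 0
    C0 <- efd$C0 %||% 0
  } else {
    cf <- efd
    A0 <- 0; C0 <- 0
  }
  tt <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  nh <- seq_len(nrow(cf))
  cosm <- cos(outer(tt, nh))
  sinm <- sin(outer(tt, nh))
  x <- A0 + cosm %*% cf[, 1] + sinm %*% cf[, 2]
  y <- C0 + cosm %*% cf[, 3] + sinm %*% cf[, 4]
  cbind(x = as.vector(x), y = as.vector(y))
}

# Accept a bare matrix or a seed_contour; return Cartesian (y-up) points.
contour_points_cartesian <- function(xy) {
  if (inherits(xy, "seed_contour")) {
    p <- xy$points
    return(cbind(p[, 1], -p[, 2]))
  }
  if (!is.matrix(xy) || ncol(xy) != 2) abort("expected an n x 2 matrix of points")
  xy
}
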