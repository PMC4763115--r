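#' @importFrom rlang %||% abort warn
#' @importFrom stats rnorm sd setNames
NULL

#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.05 -> 0.1`), the convention used by
#' most spreadsheet/statistics packages when printing percentage tables.
#' `base::round()` rounds half to even, which turns 81.25 into 81.2 rather
#' than the 81.3 a printed table shows.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(81.25, 68.75, 0.05), 1)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Signed area of a closed polygon (shoelace). Vertices as n x 2 matrix; the
# closing edge is implicit. Positive = counter-clockwise in y-up axes.
polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_perimeter <- function(xy) {
  d <- sqrt(rowSums((xy - xy[c(2:nrow(xy), 1), , drop = FALSE])^2))
  sum(d)
}

# Simplicity test for a closed polygon: checks all non-adjacent edge pairs for
# proper intersection (vectorised orientation tests). O(n^2) pairs but cheap
# at the vertex counts used for synthetic outlines.
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 4) return(TRUE)
  p1 <- xy
  p2 <- xy[c(2:n, 1), , drop = FALSE]
  idx <- utils::combn(n, 2)
  i <- idx[1, ]; j <- idx[2, ]
  # drop adjacent edges (share a vertex), including the wrap-around pair
  adj <- (j - i == 1) | (i == 1 & j == n)
  i <- i[!adj]; j <- j[!adj]
  cross2 <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  d1 <- cross2(p1[i, 1], p1[i, 2], p2[i, 1], p2[i, 2], p1[j, 1], p1[j, 2])
  d2 <- cross2(p1[i, 1], p1[i, 2], p2[i, 1], p2[i, 2], p2[j, 1], p2[j, 2])
  d3 <- cross2(p1[j, 1], p1[j, 2], p2[j, 1], p2[j, 2], p1[i, 1], p1[i, 2])
  d4 <- cross2(p1[j, 1], p1[j, 2], p2[j, 1], p2[j, 2], p2[i, 1], p2[i, 2])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

# Deterministic 31-bit string hash (polynomial, mod the Mersenne prime) used
# to derive one RNG substream per seed id, so a seed's shape does not depend
# on generation order. All intermediates stay below 2^53, so arithmetic is
# exact in doubles.
hash32 <- function(s) {
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

substream_seed <- function(master_seed, id) {
  as.integer((as.numeric(master_seed) + hash32(id)) %% .Machine$integer.max)
}
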