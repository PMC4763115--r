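#' @importFrom tibble tibble as_tibble
NULL

# Even-odd scanline fill. `poly` is an n x 2 matrix in pixel coordinates
# where pixel (row, col) has centre (x, y) = (col - 1, row - 1), y down.
# Returns integer indices into a matrix of dimension `dim` (nrow, ncol).
# A fixed sub-pixel offset avoids vertex-on-scanline degeneracies.
rasterize_polygon <- function(poly, dim) {
  eps <- 2.0000593e-4
  x <- poly[, 1] + eps
  y <- poly[, 2] + eps
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  ymin <- max(0L, floor(min(y)))
  ymax <- min(dim[1] - 1L, ceiling(max(y)))
  out <- vector("list", ymax - ymin + 1)
  for (r in ymin:ymax) {
    cross <- (y <= r & y2 > r) | (y2 <= r & y > r)
    if (!any(cross)) next
    xs <- sort(x[cross] + (r - y[cross]) * (x2[cross] - x[cross]) / (y2[cross] - y[cross]))
    cols <- unlist(lapply(seq(1, length(xs) - 1, by = 2), function(i) {
      lo <- ceiling(xs[i]); hi <- floor(xs[i + 1])
      if (hi < lo) return(integer(0))
      seq.int(lo, hi)
    }))
    cols <- cols[cols >= 0 & cols <= dim[2] - 1L]
    if (length(cols)) out[[r - ymin + 1]] <- (cols) * dim[1] + (r + 1L)
  }
  as.integer(unlist(out))
}

#' Render seed outlines into a synthetic scanner image
#'
#' Lays outlines (mm units) on a light background in a grid of equal cells,
#' filling each silhouette dark, and returns both the 8-bit image and a truth
#' table for downstream oracles. Seeds never touch the image border or each
#' other: every cell includes an internal margin.
#'
#' @param outlines list of [sample_outline()] polygons (optionally named by
#'   seed id).
#' @param dpi raster resolution (default 400, i.e. 0.0635 mm/pixel).
#' @param layout optional `c(rows, cols)`; default near-square grid.
#' @param margin_px internal margin per cell.
#' @param cell_px optional fixed cell size `c(height, width)`; an outline
#'   that does not fit raises an error naming the seed id.
#' @param fg,bg foreground (silhouette) and background gray values; the
#'   defaults mimic dark charred seeds on a scanner lid.
#' @return an object of class `seed_scene`: list with `image` (integer
#'   matrix, 0-255), `truth` (tibble: seed_id, class_label, cell_row,
#'   cell_col, centroid_x, centroid_y, area_px) and `dpi`.
#' @export
render_scene <- function(outlines, dpi = 400, layout = NULL, margin_px = 12,
                         cell_px = NULL, fg = 15L, bg = 245L) {
  if (dpi <= 0) abort("dpi must be positive")
  n <- length(outlines)
  ids <- names(outlines) %||% sprintf("seed%03d", seq_len(n))
  if (n == 0) {
    img <- matrix(as.integer(bg), 64, 64)
    return(structure(list(image = img, truth = empty_truth(), dpi = dpi),
                     class = "seed_scene"))
  }
  px_mm <- dpi / 25.4
  polys <- lapply(outlines, function(o) {
    p <- unclass(o) * px_mm
    cbind(p[, 1], -p[, 2])  # to image axes (y down)
  })
  widths <- vapply(polys, function(p) diff(range(p[, 1])), numeric(1))
  heights <- vapply(polys, function(p) diff(range(p[, 2])), numeric(1))
  need_w <- ceiling(widths) + 2 * margin_px
  need_h <- ceiling(heights) + 2 * margin_px
  if (is.null(cell_px)) {
    cell_px <- c(max(need_h), max(need_w))
  } else {
    bad <- which(need_h > cell_px[1] | need_w > cell_px[2])
    if (length(bad))
      abort(sprintf("seed %s does not fit the %dx%d px layout cell",
                    ids[bad[1]], cell_px[1], cell_px[2]))
  }
  if (is.null(layout)) {
    cols <- ceiling(sqrt(n)); rows <- ceiling(n / cols)
    layout <- c(rows, cols)
  }
  if (prod(layout) < n)
    abort(sprintf("layout %dx%d cannot hold %d seeds", layout[1], layout[2], n))

  img_dim <- c(layout[1] * cell_px[1], layout[2] * cell_px[2])
  img <- matrix(as.integer(bg), img_dim[1], img_dim[2])
  rows_out <- vector("list", n)
  for (k in seq_len(n)) {
    ci <- (k - 1) %/% layout[2]  # cell row, 0-based
    cj <- (k - 1) %% layout[2]
    p <- polys[[k]]
    ctr <- c(mean(range(p[, 1])), mean(range(p[, 2])))
    target <- c(cj * cell_px[2] + cell_px[2] / 2, ci * cell_px[1] + cell_px[1] / 2)
    p <- sweep(p, 2, ctr - target)
    idx <- rasterize_polygon(p, img_dim)
    img[idx] <- as.integer(fg)
    rr <- (idx - 1L) %% img_dim[1]        # 0-based row
    cc <- (idx - 1L) %/% img_dim[1]       # 0-based col
    o <- outlines[[k]]
    rows_out[[k]] <- tibble(
      seed_id = ids[k],
      class_label = attr(o, "params")$class_label,
      cell_row = ci + 1L, cell_col = cj + 1L,
      centroid_x = mean(cc), centroid_y = mean(rr),
      area_px = length(idx))
  }
  structure(list(image = img, truth = dplyr::bind_rows(rows_out), dpi = dpi),
            class = "seed_scene")
}

empty_truth <- function() {
  tibble(seed_id = character(), class_label = character(),
         cell_row = integer(), cell_col = integer(),
         centroid_x = numeric(), centroid_y = numeric(), area_px = integer())
}

#' @export
print.seed_scene <- function(x, ...) {
  cat(sprintf("<seed_scene> %d x %d px, %d seeds, %g dpi\n",
              nrow(x$image), ncol(x$image), nrow(x$truth), x$dpi))
  invisible(x)
}
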