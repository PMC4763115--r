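#' @importFrom ggplot2 autoplot ggplot aes geom_path geom_tile geom_text
#'   geom_raster coord_equal labs theme_minimal scale_fill_gradient
NULL

#' @export
ggplot2::autoplot

#' Plot a synthetic seed outline
#'
#' @param object a `seed_outline` from [sample_outline()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.seed_outline <- function(object, ...) {
  d <- tibble(x = object[, 1], y = object[, 2])
  d <- dplyr::bind_rows(d, d[1, ])
  ggplot(d, aes(x = .data$x, y = .data$y)) +
    geom_path() +
    coord_equal() +
    labs(x = "x (mm)", y = "y (mm)",
         title = attr(object, "params")$class_label) +
    theme_minimal()
}

#' Plot a rendered scene with its truth overlay
#'
#' @param object a `seed_scene` from [render_scene()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.seed_scene <- function(object, ...) {
  img <- object$image
  d <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  d$value <- as.vector(t(img))  # row-major to match expand_grid order
  ggplot(d, aes(x = .data$col, y = -.data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    coord_equal() +
    labs(x = NULL, y = NULL, fill = "gray") +
    theme_minimal()
}

#' Heatmap of a classification report
#'
#' @param object a `classification_report`.
#' @param ... unused.
#' @return a ggplot showing per-row assignment percentages with counts.
#' @export
autoplot.classification_report <- function(object, ...) {
  d <- as_tibble(as.data.frame.table(object$pct, responseName = "pct")) |>
    setNames(c("true_group", "pred_group", "pct"))
  d$count <- as.vector(object$counts)
  ggplot(d, aes(x = .data$pred_group, y = .data$true_group, fill = .data$pct)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.1f (%d)", .data$pct, .data$count))) +
    scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 100)) +
    labs(x = "assigned group", y = "true group", fill = "%") +
    theme_minimal()
}

#' Overlay several seed outlines
#'
#' @param outlines named list of `seed_outline` objects.
#' @return a ggplot with one path per outline, coloured by class.
#' @export
plot_outlines <- function(outlines) {
  ids <- names(outlines) %||% as.character(seq_along(outlines))
  d <- purrr::map2_dfr(outlines, ids, function(o, id) {
    tibble(id = id, class = attr(o, "params")$class_label,
           x = c(o[, 1], o[1, 1]), y = c(o[, 2], o[1, 2]))
  })
  ggplot(d, aes(x = .data$x, y = .data$y, group = .data$id,
                colour = .data$class)) +
    geom_path(alpha = 0.6) +
    coord_equal() +
    labs(x = "x (mm)", y = "y (mm)", colour = "class") +
    theme_minimal()
}
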