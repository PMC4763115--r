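#' Generate a labelled synthetic seed-scan dataset
#'
#' Renders every lot of a study design as scanner-style images (one image
#' per lot and side), mimicking the two-sided scanning protocol: each seed
#' appears exactly twice, once per side (`ventral`, `dorsal`), the dorsal
#' outline mirrored across the seed's major axis and independently
#' perturbed. Every seed draws its shape from an RNG substream keyed by its
#' id, so adding or reordering lots does not change other seeds' shapes.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   * `rng_seed` (required) integer master seed;
#'   * `dpi` raster resolution (default 400);
#'   * `separation`, `coeff_sd` passed to [seed_classes()] to build default
#'     shape classes;
#'   * `classes` optional named list of [shape_params()] overriding them;
#'   * `lots` list of lots, each with `code`, `class` (a name in `classes`),
#'     `n` (seeds), `charred` (default `FALSE`), and `group` — the label
#'     used downstream (defaults to `class`; use `"UNKNOWN"` for lots to be
#'     classified blind).
#' @param dir output directory (created if needed).
#' @return the labels tibble (one row per seed side: seed_id, lot_code,
#'   class_label, side, image_file, cell_row, cell_col, centroid_x,
#'   centroid_y, generator_class, charred), invisibly, with attribute `dir`.
#'   Side effects: per-lot-side PNGs, `labels.csv`, `manifest.yaml` in
#'   `dir`.
#' @export
make_seed_dataset <- function(config, dir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (is.null(config$rng_seed))
    abort("config$rng_seed is required: dataset generation must be reproducible")
  dpi <- config$dpi %||% 400
  classes <- config$classes %||%
    seed_classes(separation = config$separation %||% 1,
                 coeff_sd = config$coeff_sd %||% 0.02)
  classes <- lapply(classes, as_shape_params)
  if (!length(config$lots)) abort("config$lots must list at least one lot")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  labels <- list()
  for (lot in config$lots) {
    code <- lot$code %||% abort("every lot needs a code")
    cls <- lot$class %||% abort(sprintf("lot %s needs a class", code))
    if (!cls %in% names(classes))
      abort(sprintf("lot %s: unknown class '%s'", code, cls))
    params <- classes[[cls]]
    n <- lot$n %||% abort(sprintf("lot %s needs n", code))
    charred <- isTRUE(lot$charred)
    group <- lot$group %||% cls
    ids <- sprintf("%s-%03d", code, seq_len(n))

    outlines <- list(ventral = list(), dorsal = list())
    for (i in seq_len(n)) {
      set.seed(substream_seed(config$rng_seed, ids[i]))
      outlines$ventral[[ids[i]]] <- sample_outline(params, charred = charred)
      outlines$dorsal[[ids[i]]] <- sample_outline(params, charred = charred,
                                                  mirrored = TRUE)
    }
    for (side in c("ventral", "dorsal")) {
      scene <- render_scene(outlines[[side]], dpi = dpi)
      file <- sprintf("%s_%s.png", code, side)
      write_seed_image(scene, file.path(dir, file))
      labels[[length(labels) + 1L]] <- scene$truth |>
        dplyr::transmute(
          seed_id = .data$seed_id, lot_code = code, class_label = group,
          side = side, image_file = file,
          cell_row = as.integer(.data$cell_row),
          cell_col = as.integer(.data$cell_col),
          centroid_x = round(.data$centroid_x, 3),
          centroid_y = round(.data$centroid_y, 3),
          generator_class = cls, charred = charred)
    }
  }
  labels <- dplyr::bind_rows(labels)
  utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  manifest <- list(
    rng_seed = config$rng_seed, dpi = dpi,
    separation = config$separation %||% 1,
    classes = lapply(classes, unclass),
    lots = config$lots)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  attr(labels, "dir") <- dir
  invisible(labels)
}

as_shape_params <- function(x) {
  if (inherits(x, "shape_params")) return(x)
  do.call(shape_params, x)
}
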