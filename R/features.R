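#' Extract the 103-variable feature vector for every seed in an image
#'
#' End-to-end per-image extraction: binarize, label particles, trace each
#' boundary, measure the 26 shape descriptors and the 77 normalized elliptic
#' Fourier coefficients (20 harmonics). One row per particle, in reading
#' order. The contour is converted to Cartesian axes (y negated) before
#' Fourier analysis so the removed rotation angle follows the usual
#' mathematical convention.
#'
#' @param image integer gray matrix (0-255), a file path, or a `seed_scene`.
#' @param dpi raster resolution; all images of one analysis must share it.
#' @param n_harmonics harmonics for the Fourier block (default 20, giving
#'   `4 * 20 - 3 = 77` free coefficients).
#' @param min_area_px,exclude_border passed to [label_particles()].
#' @param strict_per_equiv_d passed to [measure_seed()].
#' @return tibble with columns `particle`, `centroid_x`, `centroid_y`, the
#'   26 descriptors, the 77 coefficients `d1, a2, ..., d20`, and the audit
#'   columns `E_px`, `theta_rad`, `psi_rad` (the normalization transform).
#' @export
extract_features <- function(image, dpi = 400, n_harmonics = 20,
                             min_area_px = 50, exclude_border = TRUE,
                             strict_per_equiv_d = FALSE) {
  if (inherits(image, "seed_scene")) {
    dpi <- image$dpi
    image <- image$image
  } else if (is.character(image)) {
    image <- read_seed_image(image)
  }
  fg <- binarize(image)
  seeds <- label_particles(fg, min_area_px = min_area_px,
                           exclude_border = exclude_border, dpi = dpi)
  if (!length(seeds)) return(empty_feature_table(n_harmonics))
  purrr::imap_dfr(seeds, function(sd, k) {
    ct <- trace_boundary(sd)
    morpho <- measure_seed(sd, ct, strict_per_equiv_d = strict_per_equiv_d)
    nm <- normalize_efd(compute_efd(ct, n_harmonics))
    dplyr::bind_cols(
      tibble(particle = k,
             centroid_x = sd$centroid[["x"]], centroid_y = sd$centroid[["y"]]),
      morpho,
      tibble::as_tibble_row(nm$free),
      tibble(E_px = nm$E, theta_rad = nm$theta, psi_rad = nm$psi))
  })
}

empty_feature_table <- function(n_harmonics = 20) {
  cols <- c("particle", "centroid_x", "centroid_y", morpho_names(),
            efd_names(n_harmonics), "E_px", "theta_rad", "psi_rad")
  as_tibble(setNames(rep(list(numeric(0)), length(cols)), cols))
}

#' Names of the full 103-variable feature block
#'
#' @param n_harmonics Fourier harmonic count (default 20).
#' @return character vector: the 26 descriptor names followed by the
#'   `4 * n_harmonics - 3` coefficient names (103 in total at 20 harmonics).
#' @export
feature_names <- function(n_harmonics = 20) {
  c(morpho_names(), efd_names(n_harmonics))
}

#' Extract features for a generated (or on-disk) seed dataset
#'
#' Runs [extract_features()] on every image listed in a dataset's labels
#' table and joins measurements back to seed identities by nearest truth
#' centroid (robust to reading-order differences between unequal seeds).
#'
#' @param dataset a labels tibble returned by [make_seed_dataset()], or the
#'   path of a dataset directory containing `labels.csv` and images.
#' @param dir directory holding the images when `dataset` is a tibble
#'   without a `dir` attribute.
#' @param ... passed to [extract_features()].
#' @return tibble: seed_id, lot_code, class_label, side, image_file plus the
#'   103 feature columns and audit columns.
#' @export
extract_dataset <- function(dataset, dir = NULL, ...) {
  if (is.character(dataset) && length(dataset) == 1) {
    dir <- dataset
    labels <- utils::read.csv(file.path(dir, "labels.csv"),
                              stringsAsFactors = FALSE) |> as_tibble()
  } else {
    labels <- dataset
    dir <- dir %||% attr(dataset, "dir")
    if (is.null(dir)) abort("provide `dir` (directory containing the images)")
  }
  manifest_path <- file.path(dir, "manifest.yaml")
  dpi <- if (file.exists(manifest_path))
    yaml::read_yaml(manifest_path)$dpi %||% 400 else 400

  labels |>
    dplyr::group_by(.data$image_file) |>
    dplyr::group_modify(function(lab, key) {
      feats <- extract_features(file.path(dir, key$image_file), dpi = dpi, ...)
      if (nrow(feats) != nrow(lab))
        abort(sprintf("image %s: %d particles found but %d seeds expected",
                      key$image_file, nrow(feats), nrow(lab)))
      # match particles to labelled seeds by nearest truth centroid
      d <- outer(seq_len(nrow(feats)), seq_len(nrow(lab)), function(i, j) {
        sqrt((feats$centroid_x[i] - lab$centroid_x[j])^2 +
               (feats$centroid_y[i] - lab$centroid_y[j])^2)
      })
      assign <- apply(d, 1, which.min)
      if (anyDuplicated(assign))
        abort(sprintf("image %s: ambiguous particle-to-seed matching",
                      key$image_file))
      dplyr::bind_cols(
        lab[assign, c("seed_id", "lot_code", "class_label", "side")],
        feats |> dplyr::select(-"particle"))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$seed_id, .data$side)
}
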