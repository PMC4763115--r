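#' Run the full seed identification pipeline
#'
#' Orchestrates simulate (optional) -> extract -> train -> classify ->
#' report, writing every artifact to `out_dir`: `features.csv` (metadata +
#' 103 feature columns + Fourier audit columns), `model.yaml` (selected
#' variables, coefficients, priors, trace), `assignments.csv`,
#' `report.txt`/`report.csv`, and `log.yaml` (parameters, seed, package
#' version, config hash).
#'
#' @param config list or YAML path with elements:
#'   * `simulate`: a [make_seed_dataset()] config to generate data into
#'     `<out_dir>/data` (omit when `input` is given);
#'   * `input`: one or more existing dataset directories (each with
#'     `labels.csv`, images and a `manifest.yaml`); all must share one dpi;
#'   * `lda`: list of `f_enter`, `f_remove`, `tol_min`, `priors`;
#'   * `report`: list of `include_unknown`, `expected`.
#' @param out_dir output directory.
#' @return object of class `seed_pipeline`: `features`, `fit` (a
#'   [stepwise_lda()] object), `report` (a `classification_report`),
#'   `paths`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulate)) {
    data_dir <- file.path(out_dir, "data")
    labels <- make_seed_dataset(config$simulate, data_dir)
    dirs <- data_dir
  } else if (!is.null(config$input)) {
    dirs <- config$input
  } else {
    abort("config needs either `simulate` or `input`")
  }

  dpis <- vapply(dirs, function(d) {
    mf <- file.path(d, "manifest.yaml")
    if (file.exists(mf)) as.numeric(yaml::read_yaml(mf)$dpi %||% 400) else 400
  }, numeric(1))
  if (length(unique(dpis)) > 1)
    abort(sprintf("mixed dpi across inputs (%s): features are in pixel units and must share one resolution",
                  paste(unique(dpis), collapse = ", ")))

  features <- purrr::map_dfr(dirs, extract_dataset)
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)

  lda_cfg <- config$lda %||% list()
  fit <- stepwise_lda(features,
                      f_enter = lda_cfg$f_enter %||% 3.84,
                      f_remove = lda_cfg$f_remove %||% 2.71,
                      tol_min = lda_cfg$tol_min %||% 1e-3,
                      priors = lda_cfg$priors %||% "equal")

  model_out <- list(
    variables = fit$model$variables,
    groups = fit$model$groups,
    priors = as.list(fit$model$priors),
    constants = as.list(setNames(fit$model$const, fit$model$groups)),
    coefficients = setNames(
      lapply(seq_along(fit$model$groups), function(k) as.list(
        setNames(fit$model$coef[, k], fit$model$variables))),
      fit$model$groups),
    trace = lapply(seq_len(nrow(fit$trace)), function(i) as.list(fit$trace[i, ])))
  yaml::write_yaml(model_out, file.path(out_dir, "model.yaml"))

  assignments <- fit$assignments |>
    dplyr::select(dplyr::any_of(c("seed_id", "lot_code", "class_label", "side")),
                  dplyr::starts_with(".pred"), dplyr::starts_with(".post_"))
  utils::write.csv(assignments, file.path(out_dir, "assignments.csv"),
                   row.names = FALSE)

  rep_cfg <- config$report %||% list()
  unknowns <- intersect(unique(features$class_label), fit$unknown_labels)
  report <- crosstab(fit$assignments$class_label, fit$assignments$.pred,
                     unknown = unknowns,
                     include_unknown = isTRUE(rep_cfg$include_unknown),
                     expected = rep_cfg$expected)
  writeLines(format(report), file.path(out_dir, "report.txt"))
  report_long <- as_tibble(as.data.frame.table(report$counts,
                                               responseName = "count")) |>
    setNames(c("true_group", "pred_group", "count")) |>
    dplyr::mutate(pct = as.vector(report$pct))
  utils::write.csv(report_long, file.path(out_dir, "report.csv"),
                   row.names = FALSE)

  log <- list(
    timestamp = format(Sys.time(), tz = "UTC"),
    package_version = as.character(utils::packageVersion("vitimorph")),
    dpi = unique(dpis),
    rng_seed = config$simulate$rng_seed %||% NA,
    lda = list(f_enter = lda_cfg$f_enter %||% 3.84,
               f_remove = lda_cfg$f_remove %||% 2.71,
               tol_min = lda_cfg$tol_min %||% 1e-3,
               priors = lda_cfg$priors %||% "equal"),
    config_hash = hash32(paste(deparse(config), collapse = "")),
    overall_pct = overall_pct(report))
  yaml::write_yaml(log, file.path(out_dir, "log.yaml"))

  invisible(structure(
    list(features = features, fit = fit, report = report,
         paths = file.path(out_dir, c("features.csv", "model.yaml",
                                      "assignments.csv", "report.txt",
                                      "report.csv", "log.yaml"))),
    class = "seed_pipeline"))
}

#' @export
print.seed_pipeline <- function(x, ...) {
  cat(sprintf("<seed_pipeline> %d observations, %d selected variables\n",
              nrow(x$features), length(x$fit$model$variables)))
  print(x$report)
  invisible(x)
}
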