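#' Fit linear classification functions on selected variables
#'
#' Computes per-group linear classification functions from group means and
#' the pooled within-group covariance: group `k` scores an observation `x`
#' as \deqn{s_k(x) = \mu_k' \Sigma^{-1} x - \tfrac12 \mu_k' \Sigma^{-1}
#' \mu_k + \log \pi_k,} and classification takes the argmax. Priors are
#' equal by default (`"proportional"` uses group frequencies). Rows with a
#' group label in `unknown_labels` are excluded from fitting.
#'
#' @param data data frame with the selected feature columns and group
#'   labels.
#' @param selected character vector of variable names (e.g. from
#'   [select_features()]; a `stepwise_trace` is also accepted).
#' @param group_col group label column name.
#' @param priors `"equal"`, `"proportional"`, or a named numeric vector.
#' @param unknown_labels labels excluded from fitting.
#' @return object of class `discriminant_model`: variables, group labels
#'   (sorted), per-group `means`, pooled covariance `cov` (unbiased,
#'   divisor n - g), classification `coef` (p x g) and `const` (g),
#'   `priors`, `n_k`.
#' @export
fit_discriminant <- function(data, selected, group_col = "class_label",
                             priors = c("equal", "proportional"),
                             unknown_labels = "UNKNOWN") {
  if (inherits(selected, "stepwise_trace")) selected <- attr(selected, "selected")
  if (!length(selected)) abort("no variables selected")
  grp <- data[[group_col]]
  keep <- !grp %in% unknown_labels
  data <- data[keep, , drop = FALSE]
  grp <- factor(grp[keep])  # levels sorted: the documented tie-break order
  g <- nlevels(grp)
  if (g < 2) abort("need at least 2 groups")
  missing_cols <- setdiff(selected, names(data))
  if (length(missing_cols))
    abort(sprintf("missing selected variable(s): %s",
                  paste(missing_cols, collapse = ", ")))
  X <- as.matrix(data[, selected, drop = FALSE])
  n <- nrow(X)
  n_k <- as.vector(table(grp))
  means <- rowsum(X, grp) / n_k
  Xc <- X - means[grp, , drop = FALSE]
  covw <- crossprod(Xc) / (n - g)

  if (is.character(priors)) {
    priors <- match.arg(priors)
    pri <- if (priors == "equal") rep(1 / g, g) else n_k / n
    names(pri) <- levels(grp)
  } else {
    pri <- priors[levels(grp)]
    if (anyNA(pri)) abort("named priors must cover every group")
    pri <- pri / sum(pri)
  }

  # invert via Cholesky: the same positive-definiteness criterion the
  # stepwise tolerance guard uses
  ch <- tryCatch(chol(covw), error = function(e) NULL)
  if (is.null(ch))
    abort(paste0("singular pooled covariance on variables: ",
                 paste(selected, collapse = ", ")))
  cov_inv <- chol2inv(ch)
  coef <- cov_inv %*% t(means)                      # p x g
  const <- -0.5 * colSums(t(means) * coef) + log(pri)

  structure(
    list(variables = selected, groups = levels(grp), means = means,
         cov = covw, cov_inv = cov_inv, coef = coef, const = const,
         priors = pri, n_k = setNames(n_k, levels(grp)), n = n),
    class = "discriminant_model")
}

#' Classify observations with a fitted discriminant model
#'
#' Scores every row (training, held-out or unknown alike) with the model's
#' classification functions and assigns the argmax group; ties go to the
#' first group in sorted label order. Posteriors are the softmax of the
#' scores.
#'
#' @param model a `discriminant_model`.
#' @param data data frame containing the model's variables.
#' @return `data` with added columns `.pred` (assigned group) and one
#'   posterior column `.post_<group>` per group.
#' @export
classify_seeds <- function(model, data) {
  miss <- setdiff(model$variables, names(data))
  if (length(miss))
    abort(sprintf("missing selected variable(s): %s", paste(miss, collapse = ", ")))
  X <- as.matrix(data[, model$variables, drop = FALSE])
  if (anyNA(X)) abort("feature columns must not contain missing values")
  scores <- X %*% model$coef
  scores <- sweep(scores, 2, model$const, `+`)
  pred <- model$groups[max.col(scores, ties.method = "first")]
  post <- exp(scores - apply(scores, 1, max))
  post <- post / rowSums(post)
  colnames(post) <- paste0(".post_", model$groups)
  dplyr::bind_cols(as_tibble(data), tibble(.pred = pred), as_tibble(post))
}

#' Leave-one-out cross-validation of the classification functions
#'
#' For each fitting row, refits the classification functions on all other
#' rows (the variable selection is held fixed, mirroring the classical
#' stepwise-then-LOOCV software behaviour) and classifies the held-out row.
#' Set `reselect = TRUE` for fully nested cross-validation in which the
#' stepwise selection itself is redone in every fold (slower; an honest
#' error estimate when selection optimism matters).
#'
#' @inheritParams fit_discriminant
#' @param reselect redo stepwise selection inside each fold.
#' @param ... passed to [select_features()] when `reselect = TRUE`.
#' @return tibble with one row per fitting observation: `truth`, `pred`,
#'   and `correct`.
#' @export
loocv <- function(data, selected, group_col = "class_label",
                  priors = "equal", unknown_labels = "UNKNOWN",
                  reselect = FALSE, ...) {
  if (inherits(selected, "stepwise_trace")) selected <- attr(selected, "selected")
  grp <- data[[group_col]]
  keep <- !grp %in% unknown_labels
  data <- data[keep, , drop = FALSE]
  grp <- as.character(grp[keep])
  if (any(table(grp) < 3)) abort("LOOCV needs >= 3 observations per group")
  n <- nrow(data)
  pred <- character(n)
  for (i in seq_len(n)) {
    train <- data[-i, , drop = FALSE]
    sel_i <- if (reselect)
      attr(select_features(train, group_col = group_col,
                           unknown_labels = unknown_labels, ...), "selected")
    else selected
    if (!length(sel_i)) {
      # nothing discriminates in this fold: prior-only classifier (highest
      # prior, first group in sorted label order on ties)
      pri <- if (identical(priors, "proportional")) table(train[[group_col]])
      else table(unique(train[[group_col]]))
      pred[i] <- names(pri)[which.max(pri)]
      next
    }
    m <- fit_discriminant(train, sel_i, group_col = group_col,
                          priors = priors, unknown_labels = unknown_labels)
    pred[i] <- classify_seeds(m, data[i, , drop = FALSE])$.pred
  }
  tibble(truth = grp, pred = pred, correct = grp == pred)
}

#' Stepwise linear discriminant analysis of a seed feature table
#'
#' One-shot wrapper: stepwise variable selection, discriminant fit,
#' leave-one-out cross-validation and classification of every row
#' (including unknown lots). This is the analysis a seed-morphometry study
#' runs on its assembled feature table.
#'
#' @inheritParams select_features
#' @param priors prior specification for [fit_discriminant()].
#' @param loocv run leave-one-out cross-validation (default `TRUE`).
#' @return object of class `seed_lda`: list with `trace`
#'   (`stepwise_trace`), `model` (`discriminant_model`), `assignments`
#'   (input rows with `.pred` and posteriors), `cv` (LOOCV tibble or
#'   `NULL`), `group_col`, `unknown_labels`.
#' @export
#' @examples
#' \donttest{
#' cfg <- list(rng_seed = 7, dpi = 300,
#'             lots = list(list(code = "W", class = "WILD", n = 10),
#'                         list(code = "C", class = "CULTIVATED", n = 10)))
#' d <- make_seed_dataset(cfg, tempfile("seeds"))
#' feats <- extract_dataset(d)
#' fit <- stepwise_lda(feats)
#' glance(fit)
#' }
stepwise_lda <- function(data, group_col = "class_label", features = NULL,
                         f_enter = 3.84, f_remove = 2.71, tol_min = 1e-3,
                         priors = "equal", unknown_labels = "UNKNOWN",
                         loocv = TRUE) {
  trace <- select_features(data, group_col = group_col, features = features,
                           f_enter = f_enter, f_remove = f_remove,
                           tol_min = tol_min, unknown_labels = unknown_labels)
  selected <- attr(trace, "selected")
  if (!length(selected))
    abort("stepwise selection entered no variables (all F-to-enter below threshold)")
  model <- fit_discriminant(data, selected, group_col = group_col,
                            priors = priors, unknown_labels = unknown_labels)
  assignments <- classify_seeds(model, data)
  cv <- if (loocv)
    loocv(data, selected, group_col = group_col, priors = priors,
          unknown_labels = unknown_labels)
  structure(
    list(trace = trace, model = model, assignments = assignments, cv = cv,
         group_col = group_col, unknown_labels = unknown_labels),
    class = "seed_lda")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("<discriminant_model> %d groups (%s), %d variables\n",
              length(x$groups), paste(x$groups, collapse = ", "),
              length(x$variables)))
  invisible(x)
}

#' @export
print.seed_lda <- function(x, ...) {
  sel <- x$model$variables
  cat("Stepwise linear discriminant analysis\n")
  cat(sprintf("  groups: %s\n", paste(x$model$groups, collapse = ", ")))
  cat(sprintf("  selected %d variable(s): %s\n", length(sel),
              paste(utils::head(sel, 8), collapse = ", ")))
  if (!is.null(x$cv))
    cat(sprintf("  LOOCV accuracy: %.1f%% (%d/%d)\n",
                100 * mean(x$cv$correct), sum(x$cv$correct), nrow(x$cv)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the classification-function coefficients
#'
#' @param x a `seed_lda` or `discriminant_model`.
#' @param ... unused.
#' @return tibble with columns `group`, `term` (`(Intercept)` for the
#'   constant), `estimate`.
#' @export
tidy.discriminant_model <- function(x, ...) {
  purrr::map_dfr(seq_along(x$groups), function(k) {
    tibble(group = x$groups[k],
           term = c("(Intercept)", x$variables),
           estimate = c(x$const[k], x$coef[, k]))
  })
}

#' @rdname tidy.discriminant_model
#' @export
tidy.seed_lda <- function(x, ...) tidy(x$model, ...)

#' One-row model summary
#'
#' @param x a `seed_lda` object.
#' @param ... unused.
#' @return tibble with `n`, `n_groups`, `n_selected`, `wilks_lambda` (of
#'   the final selected set), `loocv_accuracy` (proportion, `NA` if LOOCV
#'   was skipped).
#' @export
glance.seed_lda <- function(x, ...) {
  tibble(n = x$model$n,
         n_groups = length(x$model$groups),
         n_selected = length(x$model$variables),
         wilks_lambda = if (nrow(x$trace)) x$trace$wilks[nrow(x$trace)] else 1,
         loocv_accuracy = if (is.null(x$cv)) NA_real_ else mean(x$cv$correct))
}
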