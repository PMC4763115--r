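#' Stepwise variable selection by Wilks' lambda
#'
#' Greedy forward-backward selection of discriminating variables, the
#' procedure classical statistics packages run before a linear discriminant
#' analysis. Starting from the empty model, each step computes for every
#' excluded variable `x` the partial F-to-enter
#' \deqn{F = \frac{n - g - p}{g - 1}\left(\frac{\Lambda_p}{\Lambda_{p+x}} - 1\right)}
#' where `g` is the number of groups, `p` the number of entered variables
#' and `Lambda` the Wilks lambda (within-group over total generalized
#' variance) of a variable set; the largest-F variable enters if its F
#' reaches `f_enter` and its tolerance (1 - R^2 against the entered set)
#' reaches `tol_min`. After each entry, entered variables whose F-to-remove
#' drops below `f_remove` are removed. The procedure stops when no entry or
#' removal applies, or when `p` reaches `n - g - 1`. Ties are broken by the
#' frozen column order of `features`. Rows whose group is in
#' `unknown_labels` are excluded from fitting.
#'
#' @param data data frame of observations.
#' @param group_col name of the group label column.
#' @param features character vector of candidate columns, in frozen order;
#'   default: all numeric columns except obvious metadata.
#' @param f_enter,f_remove entry/removal thresholds (defaults 3.84 and
#'   2.71, the conventional chi-square/F criteria).
#' @param tol_min minimum tolerance (collinearity guard).
#' @param unknown_labels group labels treated as unknown lots (excluded
#'   from fitting).
#' @return an object of class `stepwise_trace`: tibble with columns `step`,
#'   `action` (enter/remove), `variable`, `F`, `wilks`, `tolerance`;
#'   attribute `selected` holds the final variable set (in entry order).
#' @export
select_features <- function(data, group_col = "class_label", features = NULL,
                            f_enter = 3.84, f_remove = 2.71, tol_min = 1e-3,
                            unknown_labels = "UNKNOWN") {
  grp <- data[[group_col]]
  if (is.null(grp)) abort(sprintf("column '%s' not found", group_col))
  keep <- !grp %in% unknown_labels
  data <- data[keep, , drop = FALSE]
  grp <- factor(grp[keep])
  g <- nlevels(grp)
  if (g < 2) abort("need at least 2 non-unknown groups")
  if (any(table(grp) < 2)) abort("every fitting group needs >= 2 observations")
  features <- features %||% default_feature_columns(data, group_col)
  X <- as.matrix(data[, features, drop = FALSE])
  if (anyNA(X)) abort("feature columns must not contain missing values")
  n <- nrow(X)

  # centred totals and within-group SSCP building blocks
  Xc_tot <- scale(X, center = TRUE, scale = FALSE)
  Xc_win <- X - rowsum(X, grp)[grp, , drop = FALSE] / as.vector(table(grp))[grp]
  Ttot <- crossprod(Xc_tot)
  W <- crossprod(Xc_win)

  # per-column degeneracy check (relative to the column's own magnitude)
  const <- which(diag(Ttot) <= 1e-20 * pmax(colSums(X^2), 1e-300))
  if (length(const)) {
    warn(sprintf("skipping constant feature(s): %s",
                 paste(features[const], collapse = ", ")))
  }

  # Partial residual sums of squares of candidates given an entered set E:
  # the Schur complements S_xx - S_xE S_EE^-1 S_Ex, vectorised over
  # candidates. Lambda_{E+x}/Lambda_E = (within residual)/(total residual),
  # and tolerance = (total residual)/(total SS).
  residual_ss <- function(S, E, cand) {
    if (!length(E)) return(diag(S)[cand])
    ch <- tryCatch(chol(S[E, E, drop = FALSE]), error = function(e) NULL)
    if (is.null(ch)) return(rep(NA_real_, length(cand)))
    B <- backsolve(ch, S[E, cand, drop = FALSE], transpose = TRUE)
    diag(S)[cand] - colSums(B^2)
  }
  wilks <- function(idx) {
    if (!length(idx)) return(1)
    dW <- det_psd(W[idx, idx, drop = FALSE])
    dT <- det_psd(Ttot[idx, idx, drop = FALSE])
    if (is.na(dW) || is.na(dT) || dT <= 0) return(NA_real_)
    max(dW / dT, 0)
  }

  p_all <- length(features)
  entered <- integer(0)
  lambda_cur <- 1
  trace <- list()
  step <- 0L
  repeat {
    p <- length(entered)
    if (p >= n - g - 1) break
    cand <- setdiff(seq_len(p_all), c(entered, const))
    if (!length(cand)) break
    t_res <- residual_ss(Ttot, entered, cand)
    w_res <- residual_ss(W, entered, cand)
    tol <- unname(t_res / diag(Ttot)[cand])
    # within-groups tolerance: guards the pooled covariance conditioning
    tol_w <- unname(w_res / diag(W)[cand])
    ratio <- w_res / t_res                       # Lambda_{E+x} / Lambda_E
    Fj <- unname(((n - g - p) / (g - 1)) * (1 / ratio - 1))
    ok <- !is.na(Fj) & tol >= tol_min & tol_w >= tol_min & t_res > 0
    if (!any(ok)) break
    Fj[!ok] <- -Inf
    best <- which.max(Fj)                        # frozen-order tie-break
    if (Fj[best] < f_enter) break
    entered <- c(entered, cand[best])
    lambda_cur <- unname(lambda_cur * ratio[best])
    step <- step + 1L
    trace[[length(trace) + 1L]] <- tibble(
      step = step, action = "enter", variable = features[cand[best]],
      F = Fj[best], wilks = lambda_cur, tolerance = tol[best])

    # backward pass: drop entered variables that stopped pulling weight
    repeat {
      p <- length(entered)
      if (p <= 1) break
      Fr <- vapply(seq_along(entered), function(k) {
        lam_without <- wilks(entered[-k])
        ((n - g - p + 1) / (g - 1)) * (lam_without / lambda_cur - 1)
      }, numeric(1))
      worst <- which.min(Fr)
      if (Fr[worst] >= f_remove) break
      removed <- entered[worst]
      entered <- entered[-worst]
      lambda_cur <- wilks(entered)
      step <- step + 1L
      trace[[length(trace) + 1L]] <- tibble(
        step = step, action = "remove", variable = features[removed],
        F = Fr[worst], wilks = lambda_cur,
        tolerance = NA_real_)
    }
    if (step > 4L * p_all) break  # cycling guard
  }
  out <- if (length(trace)) dplyr::bind_rows(trace) else
    tibble(step = integer(), action = character(), variable = character(),
           F = numeric(), wilks = numeric(), tolerance = numeric())
  structure(out, selected = features[entered], class = c("stepwise_trace", class(out)))
}

#' Wilks' lambda of a variable set
#'
#' Ratio of the within-group to the total generalized variance,
#' `det(W)/det(T)`, over the given variables; 1 means no separation, values
#' near 0 strong separation.
#'
#' @inheritParams select_features
#' @param vars character vector of variable names.
#' @return numeric scalar in (0, 1]; `NA` if the total SSCP is singular.
#' @export
wilks_lambda <- function(data, vars, group_col = "class_label",
                         unknown_labels = "UNKNOWN") {
  grp <- data[[group_col]]
  keep <- !grp %in% unknown_labels
  data <- data[keep, , drop = FALSE]
  grp <- factor(grp[keep])
  X <- as.matrix(data[, vars, drop = FALSE])
  Xc_tot <- scale(X, center = TRUE, scale = FALSE)
  Xc_win <- X - rowsum(X, grp)[grp, , drop = FALSE] / as.vector(table(grp))[grp]
  dW <- det_psd(crossprod(Xc_win))
  dT <- det_psd(crossprod(Xc_tot))
  if (is.na(dW) || is.na(dT) || dT <= 0) return(NA_real_)
  max(dW / dT, 0)
}

# determinant of a symmetric PSD matrix via Cholesky; NA when not PD
det_psd <- function(S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  prod(diag(ch))^2
}

default_feature_columns <- function(data, group_col) {
  drop <- c(group_col, "seed_id", "lot_code", "class_label", "side",
            "image_file", "cell_row", "cell_col", "centroid_x", "centroid_y",
            "generator_class", "charred", "particle",
            "E_px", "theta_rad", "psi_rad")
  nm <- setdiff(names(data), drop)
  nm[vapply(data[nm], is.numeric, logical(1))]
}

#' @export
print.stepwise_trace <- function(x, ...) {
  sel <- attr(x, "selected")
  cat(sprintf("<stepwise_trace> %d steps, %d variables selected\n",
              nrow(x), length(sel)))
  NextMethod()
}
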