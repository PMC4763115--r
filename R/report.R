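#' Cross-tabulate true against predicted groups
#'
#' Builds the classification report in the style archaeobotanical
#' discriminant studies print: one row per true group with the count (and
#' row percentage) assigned to each predicted group, plus a pooled overall
#' percentage. Unknown lots get their own rows showing the assignment
#' distribution; they are excluded from the pooled overall unless
#' `include_unknown = TRUE`, in which case each unknown group must declare
#' the class counted as "correct" via `expected` (a named vector or a
#' single label).
#'
#' @param truth character vector of true group labels.
#' @param pred character vector of predicted labels (training groups only).
#' @param unknown labels in `truth` that are unknown lots.
#' @param include_unknown include unknown rows in the pooled overall.
#' @param expected named character vector (or single label) giving, per
#'   unknown group, the class counted as correct when included.
#' @return object of class `classification_report`: `counts` (rows = true
#'   groups, training first, then unknown; columns = predicted groups),
#'   `pct` (half-up row percentages, 1 decimal), `row_totals`, `overall_pct`
#'   (unrounded), `overall_n`, `unknown`, `include_unknown`, `expected`.
#' @export
crosstab <- function(truth, pred, unknown = character(),
                     include_unknown = FALSE, expected = NULL) {
  if (length(truth) != length(pred))
    abort("truth and pred must have the same length")
  truth <- as.character(truth); pred <- as.character(pred)
  train_groups <- sort(setdiff(unique(truth), unknown))
  unk_groups <- sort(intersect(unique(truth), unknown))
  pred_groups <- sort(unique(c(pred, train_groups)))
  counts <- table(factor(truth, levels = c(train_groups, unk_groups)),
                  factor(pred, levels = pred_groups))
  counts <- matrix(as.integer(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  report_from_counts(counts, unknown = unk_groups,
                     include_unknown = include_unknown, expected = expected)
}

#' Build a classification report from a counts matrix
#'
#' The worked-example constructor: takes printed per-group assignment
#' counts (rows = true groups, columns = predicted groups) and computes row
#' percentages and the pooled overall exactly as [crosstab()] would.
#'
#' @param counts integer matrix with row and column names; rows for unknown
#'   groups listed via `unknown`.
#' @param correct optional named character vector mapping each training row
#'   group to the predicted column counted as correct. By default a column
#'   equal to (or a prefix of) the row name is used, so printed rows like
#'   `vinifera_untreated` pair with a `vinifera` column automatically.
#' @inheritParams crosstab
#' @return a `classification_report`.
#' @export
report_from_counts <- function(counts, unknown = character(),
                               include_unknown = FALSE, expected = NULL,
                               correct = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("counts needs row and column names")
  train <- setdiff(rownames(counts), unknown)
  ord <- c(train, intersect(rownames(counts), unknown))
  counts <- counts[ord, , drop = FALSE]
  row_totals <- rowSums(counts)
  pct <- round_half_up(100 * counts / pmax(row_totals, 1), 1)

  correct_col <- vapply(train, function(r) {
    if (!is.null(correct) && !is.null(correct[[r]])) return(correct[[r]])
    if (r %in% colnames(counts)) return(r)
    hit <- colnames(counts)[startsWith(r, colnames(counts))]
    if (length(hit)) hit[which.max(nchar(hit))] else NA_character_
  }, character(1))
  diag_idx <- cbind(match(train, rownames(counts)),
                    match(correct_col, colnames(counts)))
  if (anyNA(diag_idx))
    abort("every training group needs a matching predicted column")
  num <- sum(counts[diag_idx])
  den <- sum(row_totals[train])
  if (include_unknown && length(unknown)) {
    if (is.null(expected))
      abort("include_unknown = TRUE requires `expected` class(es) for unknown rows")
    exp_map <- if (length(expected) == 1 && is.null(names(expected)))
      setNames(rep(expected, length(unknown)), unknown) else expected
    for (u in intersect(rownames(counts), unknown)) {
      cls <- exp_map[[u]]
      if (is.null(cls) || !cls %in% colnames(counts))
        abort(sprintf("no expected class for unknown group '%s'", u))
      num <- num + counts[u, cls]
      den <- den + row_totals[u]
    }
  }
  structure(
    list(counts = counts, pct = pct, row_totals = row_totals,
         overall_pct = unname(100 * num / den), overall_n = unname(den),
         unknown = intersect(rownames(counts), unknown),
         include_unknown = include_unknown, expected = expected),
    class = "classification_report")
}

#' Overall correct-classification percentage
#'
#' @param report a `classification_report`.
#' @param digits decimals for half-up rounding; `NULL` returns unrounded.
#' @return numeric scalar, e.g. `90.4`.
#' @export
overall_pct <- function(report, digits = 1) {
  stopifnot(inherits(report, "classification_report"))
  if (is.null(digits)) report$overall_pct else round_half_up(report$overall_pct, digits)
}

#' Format a classification report as fixed-width text
#'
#' Percent-with-count convention: `94.4 (775)`, percentages half-up to one
#' decimal, row totals as `100 (n)`, pooled overall last.
#'
#' @param x a `classification_report`.
#' @param ... unused.
#' @return character vector of lines.
#' @export
format.classification_report <- function(x, ...) {
  fmt_count <- function(k) format(k, big.mark = ",", trim = TRUE, scientific = FALSE)
  cells <- matrix("", nrow(x$counts), ncol(x$counts) + 1)
  for (i in seq_len(nrow(x$counts))) {
    for (j in seq_len(ncol(x$counts))) {
      cells[i, j] <- sprintf("%.1f (%s)", x$pct[i, j], fmt_count(x$counts[i, j]))
    }
    cells[i, ncol(x$counts) + 1] <- sprintf("100 (%s)", fmt_count(x$row_totals[i]))
  }
  header <- c("", colnames(x$counts), "Total")
  body <- cbind(rownames(x$counts), cells)
  tab <- rbind(header, body)
  widths <- apply(nchar(tab), 2, max)
  lines <- apply(tab, 1, function(r) {
    paste(mapply(function(s, w) formatC(s, width = w, flag = "-"), r, widths),
          collapse = "  ")
  })
  overall <- sprintf("Overall  %.1f%% (%s)", round_half_up(x$overall_pct, 1),
                     fmt_count(x$overall_n))
  c(unname(lines), overall)
}

#' @export
print.classification_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Published cross-classification counts for grape seed lots
#'
#' Reference confusion-table counts from a published charring-and-
#' morphometry study of wild versus cultivated grape seeds (untreated lots,
#' muffle-furnace and hearth-charred lots, and a small archaeological lot
#' of 8 seeds scanned on both sides, treated as an unknown group of 16
#' cases). Used as worked examples for the report arithmetic; some printed
#' blocks are known to be internally inconsistent and are flagged.
#'
#' @return tibble with columns `table_id`, `block`, `row_group`,
#'   `row_type` (`training`/`unknown`), `pred_group`, `count`,
#'   `self_consistent` (does the block's printed overall match its counts).
#' @export
vitis_crosstab_counts <- function() {
  path <- system.file("extdata", "vitis_crosstab_counts.csv",
                      package = "vitimorph", mustWork = TRUE)
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Assemble a classification report from the published counts
#'
#' @param block a `block` value of [vitis_crosstab_counts()].
#' @inheritParams crosstab
#' @return a `classification_report`.
#' @export
vitis_report <- function(block, include_unknown = FALSE, expected = NULL) {
  d <- vitis_crosstab_counts()
  d <- d[d$block == block, , drop = FALSE]
  if (!nrow(d)) abort(sprintf("unknown block '%s'", block))
  rows <- unique(d$row_group)
  cols <- unique(d$pred_group)
  m <- matrix(0L, length(rows), length(cols), dimnames = list(rows, cols))
  m[cbind(match(d$row_group, rows), match(d$pred_group, cols))] <- d$count
  unk <- unique(d$row_group[d$row_type == "unknown"])
  report_from_counts(m, unknown = unk, include_unknown = include_unknown,
                     expected = expected)
}
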