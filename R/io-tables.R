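#' The fixed 36-column descriptor schema
#'
#' Column names of the structural descriptor, frozen as
#' base (`A`, `C`, `G`, `U`) x pairing state (`unpaired` for `.`, `open` for
#' `(`, `close` for `)`) x coordinate (`x`, `y`, `z`), in that nesting order.
#' Every feature table produced by this package uses exactly these names in
#' this order, so files are self-describing.
#'
#' @return Character vector of the 36 descriptor names.
#' @export
feature_names <- function() {
  as.vector(t(outer(
    as.vector(t(outer(c("A", "C", "G", "U"), c("unpaired", "open", "close"), paste, sep = "_"))),
    c("x", "y", "z"), paste, sep = "_"
  )))
}

#' Write / read a feature table as TSV
#'
#' The on-disk form is tab-separated text with a mandatory header of
#' `id`, `label`, then the 36 descriptor names from [feature_names()].
#' Values survive a write/read round trip to full double precision
#' (at least 12 significant digits).
#'
#' @param table A feature tibble: columns `id`, optionally `label`, and the
#'   36 descriptor columns.
#' @param path File path.
#' @return `write_feature_table()` returns `table` invisibly;
#'   `read_feature_table()` returns the feature tibble.
#' @export
write_feature_table <- function(table, path) {
  check_feature_table(table)
  if (!"label" %in% names(table)) {
    table$label <- "unlabeled"
  }
  out <- table[, c("id", "label", feature_names())]
  readr::write_tsv(out, path)
  invisible(table)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) {
    stop_input(paste0("feature table not found: ", path))
  }
  tab <- suppressWarnings(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
  expected <- c("id", "label", feature_names())
  if (!identical(names(tab), expected)) {
    stop_schema(paste0(
      "feature table at ", path, " has ", ncol(tab),
      " columns; expected the fixed 38-column schema (id, label, 36 descriptors)"
    ))
  }
  if (anyDuplicated(tab$id)) {
    stop_schema(paste0("duplicated id in feature table: ", tab$id[duplicated(tab$id)][1]))
  }
  vals <- tab[, feature_names()]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    stop_schema("feature table contains non-numeric descriptor cells")
  }
  tab
}

check_feature_table <- function(table, labeled = FALSE) {
  if (!is.data.frame(table) || !"id" %in% names(table) ||
      !all(feature_names() %in% names(table))) {
    stop_schema("expected a feature tibble with 'id' and the 36 descriptor columns")
  }
  if (labeled && !"label" %in% names(table)) {
    stop_schema("expected a labeled feature tibble (column 'label')")
  }
  invisible(table)
}

#' Write / read a cross-validation metric table as TSV
#'
#' Columns: `repetition`, `classifier`, `tp`, `fp`, `tn`, `fn`, `accuracy`,
#' `sensitivity`, `specificity`, `precision`, `recall`, `f_measure`.
#'
#' @param metrics Metric tibble (e.g. `tidy()` of a [monte_carlo_cv()] result).
#' @param path File path.
#' @export
write_metric_table <- function(metrics, path) {
  need <- c(
    "repetition", "classifier", "tp", "fp", "tn", "fn", "accuracy",
    "sensitivity", "specificity", "precision", "recall", "f_measure"
  )
  if (!all(need %in% names(metrics))) {
    stop_schema("metric table is missing required columns")
  }
  readr::write_tsv(metrics[, need], path)
  invisible(metrics)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  if (!file.exists(path)) stop_input(paste0("metric table not found: ", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
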