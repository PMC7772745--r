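#' QTL-class composition of an annotation
#'
#' Shares of each QTL class (Milk, Reproduction, Meat and Carcass, ...)
#' among the QTL records annotated within the candidate regions. By default
#' each database record counts once no matter how many candidates hit it
#' (`count = "records"`), so densely hit records do not dominate the pie;
#' `count = "rows"` counts raw annotation rows instead.
#'
#' @param annotation a QTL annotation table with `qtl_class` and `qtl_id`
#'   columns.
#' @param count `"records"` (unique `qtl_id` per class, default) or
#'   `"rows"`.
#' @return a `composition` tibble: `label`, `count`, `percent` (summing to
#'   100), sorted descending by count.
#' @export
qtl_type_composition <- function(annotation, count = c("records", "rows")) {
  count <- match.arg(count)
  ann <- strip_tbl(annotation)
  check_cols(ann, c("qtl_class", "qtl_id"), "annotation")
  if (nrow(ann) == 0) {
    warn("qtl_type_composition: empty annotation")
    return(new_composition(tibble(label = character(), count = integer(),
                                  percent = numeric())))
  }
  if (count == "records") ann <- dplyr::distinct(ann, .data$qtl_class, .data$qtl_id)
  out <- ann %>%
    dplyr::count(label = .data$qtl_class, name = "count") %>%
    dplyr::arrange(desc(.data$count), .data$label) %>%
    dplyr::mutate(percent = 100 * .data$count / sum(.data$count))
  new_composition(out)
}

#' Trait composition within one QTL class
#'
#' Per-trait shares among the annotated records of a single QTL class, e.g.
#' how much of the Reproduction class is scrotal circumference versus
#' calving ease.
#'
#' @param annotation a QTL annotation table with `qtl_class`, `trait_name`
#'   and `qtl_id` columns.
#' @param qtl_class name of the class to summarise; must be present in the
#'   annotation.
#' @inheritParams qtl_type_composition
#' @return a `composition` tibble (`label` = trait name), sorted descending.
#' @export
trait_composition <- function(annotation, qtl_class, count = c("records", "rows")) {
  count <- match.arg(count)
  ann <- strip_tbl(annotation)
  check_cols(ann, c("qtl_class", "trait_name", "qtl_id"), "annotation")
  avail <- unique(ann$qtl_class)
  if (!qtl_class %in% avail) {
    abort(sprintf("QTL class '%s' not found in annotation; available: %s",
                  qtl_class, paste(sort(avail), collapse = ", ")))
  }
  sub <- dplyr::filter(ann, .data$qtl_class == !!qtl_class)
  if (count == "records") sub <- dplyr::distinct(sub, .data$trait_name, .data$qtl_id)
  out <- sub %>%
    dplyr::count(label = .data$trait_name, name = "count") %>%
    dplyr::arrange(desc(.data$count), .data$label) %>%
    dplyr::mutate(percent = 100 * .data$count / sum(.data$count))
  new_composition(out)
}

new_composition <- function(x) {
  structure(x, class = c("composition", class(tibble())))
}

#' Incidence table for a chord diagram
#'
#' Cross-tabulates two columns of any table — typically a grouping factor
#' (study, breed, region) against an annotated feature (trait, gene) — into
#' the weighted bipartite incidence a chord diagram draws: one row per
#' observed (x, y) pair with its count. Labels are ordered alphabetically
#' within each side.
#'
#' @param rows a data frame.
#' @param x_col,y_col names of the two columns to relate; must differ.
#' @return a `chord_data` tibble: `x`, `y`, `weight` (> 0), sorted by `x`
#'   then `y`.
#' @export
relationship_data <- function(rows, x_col, y_col) {
  rows <- strip_tbl(rows)
  if (identical(x_col, y_col)) abort("`x_col` and `y_col` must be different columns")
  check_cols(rows, c(x_col, y_col), "relationship input")
  out <- tibble(x = as.character(rows[[x_col]]),
                y = as.character(rows[[y_col]])) %>%
    dplyr::count(.data$x, .data$y, name = "weight") %>%
    dplyr::arrange(.data$x, .data$y)
  structure(out, class = c("chord_data", class(tibble())))
}
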