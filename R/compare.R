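#' Overlap of annotated records among grouping factors
#'
#' Quantifies how many annotated genes or QTLs are shared between the levels
#' of a grouping factor (studies, breeds, models, traits...). IDs are
#' deduplicated within each group before intersecting, so a record annotated
#' by several markers of the same group counts once. Three square matrices
#' over the sorted group labels are returned:
#'
#' * `counts` — shared unique IDs; symmetric, with group sizes on the
#'   diagonal;
#' * `percents` — `100 * |IDs(A) ∩ IDs(B)| / |IDs(A)|` in cell (A, B).
#'   Because the denominator is the *row* group's size this matrix is in
#'   general **not** symmetric: if A has 10 unique IDs, B has 5 and they
#'   share 5, A shares 50% of its records while B shares 100%;
#' * `combined` — `"count (percent%)"` labels for display, percentages to 2
#'   decimal places.
#'
#' @param rows a data frame, typically an [annotate_loci()] result.
#' @param group_col name of the grouping column (e.g. a study label carried
#'   through from the candidate table).
#' @param id_col name of the ID column to compare (e.g. `gene_id`, or
#'   `trait_name` to compare QTLs by trait).
#' @return an `overlap_matrices` object: list with `groups`, `counts`,
#'   `percents`, `combined`. Use [generics::tidy()] for a long tibble or
#'   [plot_overlap()] for the heat map.
#' @examples
#' df <- tibble::tibble(
#'   study = rep(c("A", "B"), c(10, 5)),
#'   gene_id = c(paste0("G", 1:10), paste0("G", 1:5))
#' )
#' overlap_among_groups(df, "study", "gene_id")$percents
#' @export
overlap_among_groups <- function(rows, group_col, id_col) {
  rows <- strip_tbl(rows)
  if (identical(group_col, id_col)) {
    abort("`group_col` and `id_col` must be different columns")
  }
  check_cols(rows, c(group_col, id_col), "overlap input")

  sets <- rows %>%
    dplyr::distinct(.data[[group_col]], .data[[id_col]]) %>%
    dplyr::group_by(.data[[group_col]]) %>%
    dplyr::summarise(ids = list(.data[[id_col]]), .groups = "drop") %>%
    dplyr::arrange(.data[[group_col]])
  groups <- as.character(sets[[group_col]])
  ids <- setNames(sets$ids, groups)
  sizes <- lengths(ids)
  if (any(sizes == 0)) {
    warn("overlap_among_groups: empty group(s); their percent row is reported as 0")
  }

  k <- length(groups)
  counts <- matrix(0L, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    counts[i, j] <- length(intersect(ids[[i]], ids[[j]]))
  }
  percents <- 100 * counts / ifelse(sizes == 0, NA, sizes)  # row-wise denominator
  percents[is.na(percents)] <- 0
  combined <- matrix(
    sprintf("%d (%.2f%%)", counts, percents),
    k, k, dimnames = list(groups, groups)
  )
  structure(
    list(groups = groups, counts = counts, percents = percents,
         combined = combined),
    class = "overlap_matrices"
  )
}

#' @export
print.overlap_matrices <- function(x, ...) {
  cat(sprintf("<overlap_matrices over %d group(s)>\n", length(x$groups)))
  print(x$combined, quote = FALSE)
  invisible(x)
}

#' Tidy an overlap_matrices object
#'
#' @param x an [overlap_among_groups()] result.
#' @param ... unused.
#' @return long tibble with one row per ordered group pair: `group`,
#'   `other`, `count`, `percent` (share of `group`'s records found in
#'   `other`), `label`.
#' @export
tidy.overlap_matrices <- function(x, ...) {
  tidyr::expand_grid(group = x$groups, other = x$groups) %>%
    dplyr::mutate(
      count = as.vector(t(x$counts)),
      percent = as.vector(t(x$percents)),
      label = as.vector(t(x$combined))
    )
}

#' Plot-ready grid for the overlap heat map
#'
#' @param m an [overlap_among_groups()] result.
#' @return tibble with `group` (rows), `other` (columns), `fill` (the
#'   asymmetric percent), and `label` (the combined "count (percent%)"
#'   cell text).
#' @export
overlap_heatmap_data <- function(m) {
  stopifnot(inherits(m, "overlap_matrices"))
  tidy.overlap_matrices(m) %>%
    dplyr::rename(fill = "percent") %>%
    dplyr::select("group", "other", "fill", "label")
}
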