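# ggplot builders for each result type, plus thin file renderers.
# Every plot is a pure function of the corresponding plot-data builder
# (overlap_heatmap_data, enrichment_bubble_data, compositions, chord data);
# styling is deliberately plain.

#' Heat map of group overlap
#'
#' Tile fill is the asymmetric percentage (row group's share found in the
#' column group); cell text is the combined "count (percent%)" label.
#'
#' @param m an [overlap_among_groups()] result.
#' @return a ggplot object.
#' @export
plot_overlap <- function(m) {
  d <- overlap_heatmap_data(m)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$other, y = .data$group,
                                  fill = .data$fill)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient(low = "#fff5f0", high = "#a50f15",
                                 limits = c(0, 100), name = "% shared") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.overlap_matrices <- function(object, ...) plot_overlap(object)

#' Pie or bar chart of a composition
#'
#' @param comp a [qtl_type_composition()] or [trait_composition()] result.
#' @param style `"pie"` (class compositions) or `"bar"` (trait
#'   frequencies, descending).
#' @param top optional top-N cut for bar charts.
#' @return a ggplot object.
#' @export
plot_composition <- function(comp, style = c("pie", "bar"), top = NULL) {
  style <- match.arg(style)
  d <- as_tibble(comp)
  if (!is.null(top)) d <- dplyr::slice(d, seq_len(min(top, nrow(d))))
  if (style == "pie") {
    ggplot2::ggplot(d, ggplot2::aes(x = "", y = .data$percent, fill = .data$label)) +
      ggplot2::geom_col(width = 1, color = "white") +
      ggplot2::coord_polar(theta = "y") +
      ggplot2::labs(fill = NULL, x = NULL, y = NULL) +
      ggplot2::theme_void()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(
      x = stats::reorder(.data$label, .data$percent), y = .data$percent
    )) +
      ggplot2::geom_col(fill = "#2b8cbe") +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "% of annotated records") +
      ggplot2::theme_minimal()
  }
}

#' @export
autoplot.composition <- function(object, ...) plot_composition(object, ...)

#' Bubble plot of enrichment results
#'
#' Richness factor (k/K) on x, bubble area proportional to the annotated
#' count k, color by -log10 p.
#'
#' @param rows a [qtl_enrich()] result.
#' @inheritParams enrichment_bubble_data
#' @return a ggplot object.
#' @export
plot_enrichment <- function(rows, top = 10, p_col = c("pvalue", "adj.pval")) {
  p_col <- match.arg(p_col)
  d <- enrichment_bubble_data(rows, top = top, p_col = p_col)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$richness,
    y = stats::reorder(.data$label, .data$neglog10_p),
    size = .data$size, color = .data$neglog10_p
  )) +
    ggplot2::geom_point(alpha = 0.85) +
    ggplot2::scale_size_area(max_size = 12, name = "annotated QTLs") +
    ggplot2::scale_color_gradient(low = "#fcae91", high = "#67000d",
                                  name = expression(-log[10] ~ p)) +
    ggplot2::labs(x = "richness factor (k / K)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.qtl_enrichment <- function(object, ...) plot_enrichment(object, ...)

#' Chord diagram of a relationship
#'
#' Draws the weighted bipartite incidence from [relationship_data()] as a
#' chord diagram (via circlize when available).
#'
#' @param chord a `chord_data` tibble.
#' @return invisibly, the chord data; the diagram is drawn on the current
#'   graphics device.
#' @export
plot_relationship <- function(chord) {
  stopifnot(inherits(chord, "chord_data"))
  if (!requireNamespace("circlize", quietly = TRUE)) {
    abort("plot_relationship requires the circlize package")
  }
  circlize::circos.clear()
  circlize::chordDiagram(as.data.frame(chord[, c("x", "y", "weight")]))
  circlize::circos.clear()
  invisible(chord)
}

#' Render a plot to an image file
#'
#' Writes a ggplot (or, for chord data, a base-graphics chord diagram) to
#' PNG or SVG, inferring the device from the file extension.
#'
#' @param plot a ggplot object or a `chord_data` tibble.
#' @param path output file ending in `.png` or `.svg`.
#' @param width,height device size in inches.
#' @return `path`, invisibly.
#' @export
render_plot <- function(plot, path, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "svg")) abort("output must end in .png or .svg")
  if (ext == "png") {
    grDevices::png(path, width = width, height = height, units = "in",
                   res = 150)
  } else {
    grDevices::svg(path, width = width, height = height)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  if (inherits(plot, "chord_data")) plot_relationship(plot) else print(plot)
  invisible(path)
}
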