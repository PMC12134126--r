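#' Corn-plot layout from sample metadata
#'
#' Maps each sample's (section_index, zipcode) position to plotting
#' coordinates of the stylized corn plot: zipcodes as ordered columns
#' (canonical anatomical order), sections as rows from anterior (top) to
#' posterior (bottom).  The layout is deterministic per stage.
#'
#' @param meta sample metadata with section_index and zipcode.
#' @return Tibble: sample_id, zipcode, section_index, x, y.
#' @export
cornplot_layout <- function(meta) {
  if (!all(c("sample_id", "section_index", "zipcode") %in% names(meta))) {
    arg_error("`meta` needs sample_id, section_index, zipcode.")
  }
  zips <- intersect(ZIPCODES, unique(meta$zipcode))
  extra <- setdiff(unique(meta$zipcode), zips)
  levels <- c(zips, sort(extra))
  tibble(sample_id = meta$sample_id, zipcode = meta$zipcode,
         section_index = meta$section_index,
         x = match(meta$zipcode, levels),
         y = -meta$section_index)
}

## per-sample plotted value: mean expression of the requested genes
cornplot_values <- function(expr, meta, genes) {
  missing <- setdiff(genes, expr$gene_id)
  if (length(missing) > 0) {
    arg_error(sprintf("Unknown gene(s): %s",
                      paste(head(missing, 5), collapse = ", ")))
  }
  m <- expr_mat(filter_genes(expr, genes))
  layout <- cornplot_layout(meta)
  layout$value <- colMeans(m)[layout$sample_id]
  layout
}

#' Corn plot of a gene or gene group
#'
#' Renders the average expression of `genes` over the corn-plot layout as a
#' kernel grid, one glyph per sample, color monotone in expression.
#'
#' @param expr expression tibble (any scale; plotted as-is).
#' @param meta sample metadata with section_index and zipcode.
#' @param genes gene id(s) to average.
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
plot_cornplot <- function(expr, meta, genes, title = NULL) {
  vals <- cornplot_values(expr, meta, genes)
  ggplot2::ggplot(vals, ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$value)) +
    ggplot2::geom_point(shape = 21, size = 6, colour = "grey30") +
    ggplot2::scale_x_continuous(breaks = sort(unique(vals$x)),
                                labels = vals$zipcode[
                                  match(sort(unique(vals$x)), vals$x)]) +
    ggplot2::scale_y_continuous(breaks = sort(unique(vals$y)),
                                labels = -sort(unique(vals$y))) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "zipcode", y = "section (anterior → posterior)",
                  fill = "expr",
                  title = title %||% paste(head(genes, 3), collapse = ", ")) +
    ggplot2::theme_minimal()
}

#' Render a corn plot to disk
#'
#' Writes `<out_prefix>.png` and a deterministic `<out_prefix>.tsv` of the
#' plotted per-sample values.
#'
#' @inheritParams plot_cornplot
#' @param out_prefix output path prefix.
#' @return Invisibly, the two file paths.
#' @export
render_cornplot <- function(expr, meta, genes, out_prefix, title = NULL) {
  vals <- cornplot_values(expr, meta, genes)
  tsv <- paste0(out_prefix, ".tsv")
  png <- paste0(out_prefix, ".png")
  readr::write_tsv(vals, tsv)
  p <- plot_cornplot(expr, meta, genes, title = title)
  suppressMessages(ggplot2::ggsave(png, p, width = 6, height = 5, dpi = 120))
  invisible(c(png = png, tsv = tsv))
}
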