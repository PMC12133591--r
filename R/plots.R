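#' Volcano plot of per-PDX enrichment results
#'
#' log2 fold change (biot minus nb) against -log10 permutation p-value,
#' colored by the detection call and faceted by PDX.
#'
#' @param object A `surface_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.surface_calls <- function(object, ...) {
  df <- tibble::as_tibble(unclass_result(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p_value),
                                   colour = .data$detected)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$pdx_id)) +
    ggplot2::labs(x = "log2 fold change (biot - nb)",
                  y = "-log10 permutation p",
                  colour = "detected") +
    ggplot2::theme_bw()
}

#' Waterfall plot of the triage cascade
#'
#' Surviving-protein counts after each triage stage.
#'
#' @param object A `candidate_triage` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.candidate_triage <- function(object, ...) {
  wf <- attr(object, "waterfall")
  wf$stage <- factor(wf$stage, levels = wf$stage)
  ggplot2::ggplot(wf, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "proteins surviving") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Dot plot of cell-type expression for selected genes
#'
#' The single-cell-atlas view behind the cell-type exclusion stage: dot
#' size is the fraction of cells expressing the gene, color its mean
#' expression level.
#'
#' @param atlas An [expression_atlas()] (or celltype summary tibble).
#' @param genes Character vector of gene symbols.
#' @return A ggplot object.
#' @export
plot_dotplot <- function(atlas, genes) {
  df <- purrr::map_dfr(genes, function(g) {
    dplyr::mutate(dotplot_stats(atlas, g), gene_symbol = g)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$celltype, y = .data$gene_symbol,
                                   size = .data$frac_expressing,
                                   colour = .data$mean_expr)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "grey85", high = "purple4") +
    ggplot2::scale_size_area(max_size = 8, limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, size = "fraction expressing",
                  colour = "mean expression") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
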