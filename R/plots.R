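# ggplot2 summaries for the main result types.

#' Volcano-style view of per-gene clinical associations
#'
#' Continuity-corrected odds ratio (log2) against -log10 Fisher p, coloured
#' by structural category. Unmutated genes are dropped.
#'
#' @param assoc Tibble from [associate_genes()].
#' @param alpha Dashed significance guide line. Default 0.05.
#' @return A ggplot object.
#' @export
plot_gene_associations <- function(assoc, alpha = 0.05) {
  df <- filter(assoc, .data$category != "unmutated")
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$or_corrected),
                                   y = -log10(.data$p),
                                   colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "log2 odds ratio (continuity-corrected)",
                  y = "-log10 Fisher p", colour = "category") +
    ggplot2::theme_minimal()
}

#' Cell-line support breakdown of an integrated set
#'
#' @param x An `integrated_set` from [intersect_sets()].
#' @return A ggplot bar chart of the [condition_breakdown()] groups.
#' @export
plot_condition_breakdown <- function(x) {
  bd <- condition_breakdown(x)
  ggplot2::ggplot(bd, ggplot2::aes(x = .data$group, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3) +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Screen support of integrated resistance genes") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.integrated_set <- function(object, ...) {
  plot_condition_breakdown(object)
}

#' Resistance matrix heatmap
#'
#' Tile view of the significant, screen-supported genes (rows, ordered by
#' clinical p) against screened conditions, with selection flags as fill.
#'
#' @param x A `resistance_matrix` from [significant_cluster()].
#' @return A ggplot object.
#' @export
plot_resistance_matrix <- function(x) {
  long <- tidy(x)
  long$gene <- factor(long$gene, levels = rev(rownames(x$mat)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$gene,
                                     fill = .data$selected)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey95")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "resistant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.resistance_matrix <- function(object, ...) {
  plot_resistance_matrix(object)
}

#' Over-representation dot plot
#'
#' @param enrichment Tibble from [ora()].
#' @param top_n Number of top terms (by p) shown. Default 15.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, top_n = 15) {
  df <- utils::head(arrange(enrichment, .data$p), top_n)
  df$name <- factor(df$name, levels = rev(df$name))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_ratio, y = .data$name,
                                   size = .data$k, colour = .data$p)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "firebrick", high = "steelblue") +
    ggplot2::labs(x = "gene ratio", y = NULL, size = "hits", colour = "p") +
    ggplot2::theme_minimal()
}
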