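#' Dot plot of the top marker genes per cell type
#'
#' Shows, for each target type, the `n` best genes by Mean Ratio (or by
#' standardized log fold change for one-vs-all statistics) with the ratio on
#' the x axis, mirroring the usual marker-selection summary figure.
#'
#' @param object A `marker_stats` tibble.
#' @param n Genes per type to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.marker_stats <- function(object, n = 5, ...) {
  value <- if ("mean_ratio" %in% names(object)) "mean_ratio" else "std_logfc"
  rank_col <- if (value == "mean_ratio") "rank_ratio" else "rank_fc"
  top <- object %>%
    filter(.data[[rank_col]] <= n) %>%
    mutate(val = ifelse(is.finite(.data[[value]]), .data[[value]], NA_real_))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$val,
                                    y = stats::reorder(.data$gene,
                                                       -.data[[rank_col]]))) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~cell_type, scales = "free_y") +
    ggplot2::labs(x = value, y = NULL,
                  title = paste("Top", n, "marker genes per cell type")) +
    ggplot2::theme_bw()
}

#' Stacked composition bar plot of a proportion table
#'
#' @param object A [proportion_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.proportion_table <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$sample, y = .data$proportion,
                               fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion", fill = "cell type") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Predicted vs measured proportion scatter with metric annotation
#'
#' The benchmark's standard accuracy view: each point is one
#' (sample, cell type) pair, the dashed line is the identity, and the
#' annotation reports the pooled Pearson correlation and rmse.
#'
#' @param pred A [proportion_table()].
#' @param ref A [composition_table()] or proportion-like reference (same
#'   conventions as [evaluate_against_reference()]).
#' @param merge_map Passed to [merge_types()] before pairing (default
#'   collapses the oligodendrocyte lineage).
#' @return A ggplot object.
#' @export
plot_proportion_scatter <- function(pred, ref,
                                    merge_map = list(OligoOPC = c("Oligo", "OPC"))) {
  if (!is.null(merge_map)) {
    have <- proportion_types(pred)
    applicable <- purrr::keep(merge_map, ~ length(intersect(.x, have)) > 0)
    if (length(applicable) > 0) pred <- merge_types(pred, applicable)
  }
  pred_long <- tidy(pred) %>%
    select("sample", "cell_type", pred = "proportion")
  ref_long <- reference_long(ref) %>%
    filter(.data$cell_type != "Other") %>%
    rename(sample = "ref_key")
  paired <- inner_join(pred_long, ref_long, by = c("sample", "cell_type"))
  met <- metric_suite(paired$pred, paired$ref)
  lab <- sprintf("cor = %.3f, rmse = %.3f", met$cor, met$rmse)
  ggplot2::ggplot(paired, ggplot2::aes(x = .data$ref, y = .data$pred,
                                       colour = .data$cell_type)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                      label = lab) +
    ggplot2::labs(x = "measured proportion", y = "predicted proportion",
                  colour = "cell type") +
    ggplot2::theme_bw()
}

#' Marker-gene expression heatmap (z-scored log CPM of pseudobulk)
#'
#' Rows are marker genes (grouped by the type they mark), columns are
#' pseudobulk groups; colour is the per-gene z-score of log2 CPM, so each
#' gene's variation across groups is on a common scale.
#'
#' @param pb A `pseudobulk_set` grouped by (at least) `cell_type`.
#' @param markers A [marker_set()].
#' @param n Markers per type to display.
#' @return A ggplot object.
#' @export
plot_marker_heatmap <- function(pb, markers, n = 5) {
  sel <- tidy(markers) %>% filter(.data$rank <= n)
  z <- zscore_by_gene(logcpm(pb))
  sel <- sel[sel$gene %in% rownames(z), ]
  df <- as_tibble(z[sel$gene, , drop = FALSE], rownames = "gene") %>%
    tidyr::pivot_longer(-"gene", names_to = "group",
                        values_to = "zscore") %>%
    left_join(select(sel, "gene", marker_of = "cell_type"), by = "gene") %>%
    mutate(gene = factor(.data$gene, levels = rev(sel$gene)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$gene,
                                   fill = .data$zscore)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$marker_of),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z-score") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Heatmap of pairwise method concordance
#'
#' @param object A `concordance_matrix` from [pairwise_concordance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.concordance_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$method_a, y = .data$method_b,
                               fill = .data$cor)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$cor)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_bw()
}
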