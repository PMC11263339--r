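#' MA-style plot of a DE comparison
#'
#' Mean expression (average of the two prior-damped group means, log10)
#' against log2 fold change, colored by the pair category of the
#' classification tree.
#'
#' @param de An `ix_de` table.
#' @param t An `ix_thresholds`.
#' @return A ggplot object.
#' @export
plot_ma <- function(de, t = thresholds()) {
  cats <- categorize_pair(de, t)
  df <- left_join(as_tibble(de), cats, by = "gene_id")
  df <- mutate(df, mean_expr = (.data$mean_fpkm_a + .data$mean_fpkm_b) / 2 + 0.25)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_expr, y = .data$log2fc,
                                   colour = .data$category)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_hline(yintercept = c(-t$lfc, t$lfc), linetype = "dashed") +
    ggplot2::labs(x = "mean group FPKM (prior-damped)", y = "log2 fold change",
                  colour = "category",
                  title = attr(de, "comparison") %||% "comparison") +
    ggplot2::theme_minimal()
}

#' Cluster membership sizes
#'
#' @param membership `ix_membership` from [build_all_clusters()].
#' @return A ggplot bar chart of subtype counts per cluster (low/none
#'   omitted).
#' @export
plot_cluster_sizes <- function(membership) {
  df <- filter(as_tibble(membership), !.data$subtype %in% c("none", "low"))
  df <- count(df, .data$cluster, .data$subtype)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subtype, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~cluster, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Pattern-label counts for one gene group
#'
#' @param summary Tibble (`pattern`, `n`) from [summarize_patterns()].
#' @param group Optional group name for the title.
#' @return A ggplot bar chart.
#' @export
plot_pattern_summary <- function(summary, group = NULL) {
  summary$pattern <- factor(summary$pattern,
                            levels = c("no_change", "downregulation",
                                       "upregulation", "other"))
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$pattern, y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "genes", title = group) +
    ggplot2::theme_minimal()
}

#' Mosaic plot of a contingency table
#'
#' Column widths proportional to row totals, segment heights to within-row
#' shares — the usual display for pupa-type versus adult-class association.
#'
#' @param t An `ix_contingency`.
#' @return A ggplot object.
#' @export
plot_mosaic <- function(t) {
  df <- tidy(t)
  names(df)[1:2] <- c("row", "col")
  df <- group_by(df, .data$row)
  df <- mutate(df, row_total = sum(.data$observed))
  df <- ungroup(df)
  rows <- distinct(df, .data$row, .data$row_total)
  rows <- mutate(rows, xmax = cumsum(.data$row_total) / sum(.data$row_total),
                 xmin = dplyr::lag(.data$xmax, default = 0))
  df <- left_join(df, select(rows, "row", "xmin", "xmax"), by = "row")
  df <- group_by(df, .data$row)
  df <- mutate(df, ymax = cumsum(.data$row_prop),
               ymin = dplyr::lag(.data$ymax, default = 0))
  df <- ungroup(df)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$col),
                       colour = "white") +
    ggplot2::scale_x_continuous(
      breaks = (rows$xmin + rows$xmax) / 2, labels = rows$row) +
    ggplot2::labs(x = t$row_var, y = "proportion", fill = t$col_var) +
    ggplot2::theme_minimal()
}
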