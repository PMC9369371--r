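# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of a differential-expression screen
#'
#' @param object A `de_table` from [call_sdels()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot de_table
#' @export
autoplot.de_table <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$log2fc, -log10(.data$q_value),
                                  colour = .data$regulation)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(up = "#d7301f", down = "#0570b0", ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 q-value",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Layered layout of a ceRNA network
#'
#' Draws the tripartite graph with one column per RNA class, node colour by
#' regulation and size by degree.
#'
#' @param object A [cerna_graph].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cerna_graph
#' @export
autoplot.cerna_graph <- function(object, ...) {
  g <- if ("degree" %in% names(object$nodes)) object else centralities(object)
  nodes <- network_nodes(g) |>
    mutate(x = match(.data$node_class, c("lncRNA", "miRNA", "mRNA"))) |>
    group_by(.data$node_class) |>
    arrange(.data$node_id, .by_group = TRUE) |>
    mutate(y = seq(0, 1, length.out = max(dplyr::n(), 2))[seq_len(dplyr::n())]) |>
    ungroup()
  pos <- nodes[, c("node_id", "x", "y")]
  edges <- network_edges(g) |>
    left_join(pos, by = c(source_id = "node_id")) |>
    left_join(pos, by = c(target_id = "node_id"), suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey80", linewidth = 0.3) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, colour = .data$regulation,
                   shape = .data$node_class, size = .data$degree)) +
    ggplot2::scale_colour_manual(
      values = c(up = "#d7301f", down = "#0570b0"), na.value = "grey50") +
    ggplot2::scale_x_continuous(breaks = 1:3,
                                labels = c("lncRNA", "miRNA", "mRNA"),
                                limits = c(0.5, 3.5)) +
    ggplot2::labs(x = NULL, y = NULL, size = "degree") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Bubble chart of top enriched terms
#'
#' @param object An `ora_result` from [run_ora()].
#' @param k Terms per category to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ora_result
#' @export
autoplot.ora_result <- function(object, k = 10, ...) {
  d <- top_k_per_category(object, k)
  d$term <- stats::reorder(paste0(d$term_id, ": ", d$term_name), -d$p_value)
  ggplot2::ggplot(d, ggplot2::aes(-log10(.data$p_value), .data$term,
                                  size = .data$k, colour = .data$q_value)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$category), scales = "free_y") +
    ggplot2::labs(x = "-log10 p-value", y = NULL,
                  size = "genes", colour = "q-value") +
    ggplot2::theme_minimal()
}

#' Relative-expression bars for qPCR results
#'
#' @param object A `ddct_result` (or row-bound tibble of them).
#' @param ... Unused.
#' @return A ggplot showing 2^-ddCt per gene (control = 1, dashed line).
#' @method autoplot ddct_result
#' @export
autoplot.ddct_result <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$gene_id, .data$rel_expr,
                                  fill = .data$fold_direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_fill_manual(
      values = c(up = "#d7301f", down = "#0570b0", unchanged = "grey60")) +
    ggplot2::labs(x = NULL, y = "relative expression (2^-ddCt)", fill = NULL) +
    ggplot2::theme_minimal()
}
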