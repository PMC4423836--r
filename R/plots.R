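#' Plot a similarity graph
#'
#' Draws the graph with a deterministic force-directed layout (seeded
#' Fruchterman-Reingold via igraph); edge width tracks similarity, node
#' colour distinguishes outcome nodes (`Event`/`No_Event`) from indicator
#' nodes.
#'
#' @param object A `"cm_graph"`.
#' @param seed Layout seed (default 1).
#' @param label_size Node label size (default 2.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cm_graph <- function(object, seed = 1L, label_size = 2.5, ...) {
  ig <- as_igraph(object)
  xy <- with_preserved_seed(seed, igraph::layout_with_fr(ig))
  nodes <- tibble(node = object$nodes, x = xy[, 1], y = xy[, 2],
                  outcome = object$nodes %in% c("Event", "No_Event"))
  edges <- object$edges %>%
    left_join(nodes[, c("node", "x", "y")], by = c(from = "node")) %>%
    rename(x1 = "x", y1 = "y") %>%
    left_join(nodes[, c("node", "x", "y")], by = c(to = "node")) %>%
    rename(x2 = "x", y2 = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                   yend = .data$y2, linewidth = .data$weight),
      colour = "grey55") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$outcome),
      size = 3, show.legend = FALSE) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
      vjust = -1, size = label_size) +
    ggplot2::scale_linewidth(range = c(0.2, 1.4), guide = "none") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "firebrick")) +
    ggplot2::theme_void()
}

#' Plot a fitness trace
#'
#' Best-ever and population-mean fitness by generation for a TWIST search.
#'
#' @param object A `"twist_mask"` or `"twist_split"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.twist_mask <- function(object, ...) {
  trace <- tidyr::pivot_longer(object$trace, c("best_fitness", "mean_fitness"),
                               names_to = "series", values_to = "fitness")
  ggplot2::ggplot(trace,
                  ggplot2::aes(x = .data$generation, y = .data$fitness,
                               colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "held-out fitness",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.twist_mask
#' @export
autoplot.twist_split <- autoplot.twist_mask

#' Plot a similarity matrix
#'
#' Heat map of the Auto-CM similarity matrix, rows and columns in the
#' training column order.
#'
#' @param object A trained `"autocm_model"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.autocm_model <- function(object, ...) {
  S <- similarity_matrix(object)
  df <- as_tibble(as.data.frame(as.table(unclass(S))))
  names(df) <- c("var1", "var2", "similarity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var1, y = .data$var2,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1))
}
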