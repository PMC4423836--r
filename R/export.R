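#' Convert to an igraph object
#'
#' Node attributes carry the parent variable and category when `info` is
#' supplied; edge attributes carry the similarity weight and, for Meta-MST
#' graphs, the support count.
#'
#' @param g A `"cm_graph"`.
#' @param info Optional [indicator_info()] tibble for node attributes.
#' @return An igraph graph.
#' @export
as_igraph <- function(g, info = NULL) {
  vertices <- tibble(name = g$nodes)
  if (!is.null(info)) {
    vertices <- left_join(vertices,
                          info[, c("column", "parent", "category_label")],
                          by = c(name = "column"))
    vertices$parent[is.na(vertices$parent)] <- ""
    vertices$category_label[is.na(vertices$category_label)] <- ""
  }
  vertices$degree <- as.integer(graph_degrees(g)[vertices$name])
  igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                vertices = vertices)
}

#' Write a graph as GraphML or DOT
#'
#' @param g A `"cm_graph"`.
#' @param path Output path.
#' @param info Optional [indicator_info()] tibble for node attributes.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path, info = NULL) {
  igraph::write_graph(as_igraph(g, info), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_dot <- function(g, path, info = NULL) {
  igraph::write_graph(as_igraph(g, info), path, format = "dot")
  invisible(path)
}

#' Write an edge list as CSV
#'
#' @param g A `"cm_graph"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  readr::write_csv(g$edges, path, progress = FALSE)
  invisible(path)
}
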