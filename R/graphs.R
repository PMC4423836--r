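#' Weighted undirected graphs over indicator variables
#'
#' Graphs produced by the similarity-network stage are stored as a plain
#' list: `nodes` (character labels), `edges` (tibble with `from`, `to`,
#' `weight` and optionally `support`; `from < to` lexicographically, no
#' self-loops), and `is_tree`. Edge weights are similarities in `[0, 1]`.
#'
#' @param nodes Character vector of node labels.
#' @param edges Tibble with columns `from`, `to`, `weight`.
#' @param is_tree Logical flag.
#' @return An object of class `"cm_graph"`.
#' @export
cm_graph <- function(nodes, edges, is_tree = FALSE) {
  edges <- as_tibble(edges)
  if (nrow(edges) > 0) {
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    if (any(edges$from == edges$to)) {
      abort("Self-loops are not allowed.", class = "twistmap_error_graph")
    }
    edges <- edges[order(edges$from, edges$to, method = "radix"), ]
  }
  structure(list(nodes = nodes, edges = edges, is_tree = is_tree),
            class = "cm_graph")
}

#' @export
print.cm_graph <- function(x, ...) {
  cat(sprintf("%s with %d nodes and %d edges\n",
              if (x$is_tree) "Tree" else "Graph",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Node degrees of a graph
#'
#' @param g A `"cm_graph"`.
#' @return Named integer vector over all nodes (isolated nodes have 0).
#' @export
graph_degrees <- function(g) {
  d <- setNames(integer(length(g$nodes)), g$nodes)
  if (nrow(g$edges) > 0) {
    tab <- table(c(g$edges$from, g$edges$to))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

graph_is_connected <- function(g) {
  n <- length(g$nodes)
  if (n <= 1) return(TRUE)
  if (nrow(g$edges) < n - 1) return(FALSE)
  comp <- components_of(g)
  max(comp) == 1
}

# Connected-component index per node (BFS over the edge list).
components_of <- function(g) {
  idx <- setNames(seq_along(g$nodes), g$nodes)
  adj <- split(c(g$edges$to, g$edges$from),
               factor(c(g$edges$from, g$edges$to), levels = g$nodes))
  comp <- setNames(rep(NA_integer_, length(g$nodes)), g$nodes)
  cid <- 0L
  for (start in g$nodes) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      nb <- adj[[u]]
      new <- nb[is.na(comp[nb])]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  comp
}

#' Minimum spanning tree of a distance matrix
#'
#' Kruskal's algorithm with deterministic tie-breaking: edges are sorted by
#' distance, ties broken by the lexicographic order of their node-label
#' pair. The result links every variable into a single acyclic graph of
#' `N - 1` edges with minimal total distance (equivalently maximal total
#' similarity); every link that would close a cycle is eliminated,
#' whatever its strength.
#'
#' @param D Symmetric finite distance matrix with dimnames (typically
#'   [to_distances()] of an Auto-CM similarity matrix).
#' @return A `"cm_graph"` tree whose edge `weight` column holds the
#'   similarity `1 - d`.
#' @export
minimum_spanning_tree <- function(D) {
  D <- unclass(as.matrix(D))
  if (!isSymmetric(unname(D)) || any(!is.finite(D))) {
    abort("Distance matrix must be symmetric and finite.",
          class = "twistmap_error_graph")
  }
  n <- nrow(D)
  labels <- rownames(D) %||% paste0("V", seq_len(n))
  iu <- which(upper.tri(D), arr.ind = TRUE)
  from <- pmin(labels[iu[, 1]], labels[iu[, 2]])
  to <- pmax(labels[iu[, 1]], labels[iu[, 2]])
  w <- D[iu]
  ord <- order(w, from, to, method = "radix")
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  take <- logical(length(ord))
  picked <- 0L
  pos <- setNames(seq_len(n), labels)
  for (e in ord) {
    a <- find(pos[from[e]]); b <- find(pos[to[e]])
    if (a != b) {
      parent[a] <- b
      take[e] <- TRUE
      picked <- picked + 1L
      if (picked == n - 1L) break
    }
  }
  if (picked < n - 1L) {
    abort("Distance matrix does not define a connected graph.",
          class = "twistmap_error_graph")
  }
  keep <- which(take)
  cm_graph(labels,
           tibble(from = from[keep], to = to[keep], weight = 1 - w[keep]),
           is_tree = TRUE)
}

#' Hubness index H
#'
#' A normalised summary of how concentrated connectivity is in high-degree
#' nodes: `H = sum_i max(0, deg_i - 2) / (N - 2)`. A path scores 0; a star
#' on `N` nodes scores `(N - 3) / (N - 2)`, approaching 1.
#'
#' @param g A connected `"cm_graph"` with at least 3 nodes.
#' @return `H` in `[0, 1]`... and beyond 1 only for multigraphs, which are
#'   excluded by construction.
#' @export
h_index <- function(g) {
  n <- length(g$nodes)
  if (n < 3) {
    abort("H is defined for graphs with at least 3 nodes.",
          class = "twistmap_error_graph")
  }
  if (!graph_is_connected(g)) {
    abort("H is defined for connected graphs.",
          class = "twistmap_error_graph")
  }
  d <- graph_degrees(g)
  sum(pmax(d - 2, 0)) / (n - 2)
}

#' Number of pruning cycles to delete a graph
#'
#' Repeatedly deletes all nodes of degree at most 1 (leaf waves); when only
#' cycles remain, deletes all nodes of the current minimum degree per wave.
#' The number of waves needed to empty the graph measures its depth: trees
#' vanish in few leaf waves, nested cyclic structure resists longer.
#'
#' @param g A nonempty `"cm_graph"`.
#' @return Integer `P >= 1`.
#' @export
pruning_cycles <- function(g) {
  nodes <- g$nodes
  if (length(nodes) == 0) {
    abort("Pruning an empty graph.", class = "twistmap_error_graph")
  }
  edges <- g$edges
  p <- 0L
  while (length(nodes) > 0) {
    d <- setNames(integer(length(nodes)), nodes)
    if (nrow(edges) > 0) {
      tab <- table(c(edges$from, edges$to))
      d[names(tab)] <- as.integer(tab)
    }
    drop <- if (min(d) <= 1) names(d)[d <= 1] else names(d)[d == min(d)]
    nodes <- setdiff(nodes, drop)
    if (nrow(edges) > 0) {
      edges <- edges[!(edges$from %in% drop) & !(edges$to %in% drop), ]
    }
    p <- p + 1L
  }
  p
}

#' Topological entropy of a graph
#'
#' `E_G = (A / P) * H_S`: the number of arcs per pruning cycle, weighted by
#' the Shannon information of the degree distribution
#' (`H_S = -sum_i p_i log2 p_i` with `p_i = deg_i / sum_j deg_j`). Denser
#' graphs that survive more pruning and spread their connectivity over many
#' nodes score higher.
#'
#' @param g A connected `"cm_graph"` with at least 2 nodes.
#' @return `E_G` (dimensionless).
#' @export
topological_entropy <- function(g) {
  if (length(g$nodes) < 2 || !graph_is_connected(g)) {
    abort("E_G is defined for connected graphs with >= 2 nodes.",
          class = "twistmap_error_graph")
  }
  d <- graph_degrees(g)
  p <- d / sum(d)
  hs <- -sum(p * log2(p))
  (nrow(g$edges) / pruning_cycles(g)) * hs
}

#' Complexity report of a graph
#'
#' @param g A `"cm_graph"`.
#' @return A list of class `"complexity_report"`: `H` (NA when undefined),
#'   `E_G` (NA when undefined), arc count `A`, pruning cycles `P`, and the
#'   `degree_histogram` tibble.
#' @export
complexity_report <- function(g) {
  d <- graph_degrees(g)
  conn <- graph_is_connected(g)
  H <- if (length(g$nodes) >= 3 && conn) h_index(g) else NA_real_
  EG <- if (length(g$nodes) >= 2 && conn) topological_entropy(g) else NA_real_
  hist <- count(tibble(degree = as.integer(d)), .data$degree, name = "count")
  structure(list(H = H, E_G = EG, A = nrow(g$edges), P = pruning_cycles(g),
                 degree_histogram = hist, degrees = d),
            class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("Graph complexity: H = %.3f, E_G = %.3f, A = %d, P = %d\n",
              x$H, x$E_G, x$A, x$P))
  invisible(x)
}

#' Maximally regular graph
#'
#' Re-introduces into the MST the strongest links it had eliminated:
#' candidate non-tree pairs with similarity above `floor` are sorted by
#' descending similarity and added one at a time to a copy of the tree,
#' recording the hubness `H` after each addition. The returned graph is the
#' one of maximal `H` along this sequence (earliest on ties), so the search
#' maximises the number of re-added connections while keeping the original
#' tree as a subgraph; cyclic regular microstructures become visible.
#'
#' @param S Similarity matrix (the one the MST was built from).
#' @param mst The MST as a `"cm_graph"`; computed from `S` when `NULL`.
#' @param floor Minimum similarity for a link to be re-introduced (default
#'   0.33, the null/very-low bound: re-added links should not be
#'   noise-level).
#' @return A list of class `"mrg_result"`: `graph` (the MRG), `report`
#'   (its [complexity_report()]), `mst_report`, `n_candidates`, `n_added`.
#' @export
maximally_regular_graph <- function(S, mst = NULL, floor = 0.33) {
  S <- unclass(as.matrix(S))
  if (is.null(mst)) mst <- minimum_spanning_tree(to_distances(S))
  labels <- mst$nodes
  iu <- which(upper.tri(S), arr.ind = TRUE)
  from <- pmin(labels[iu[, 1]], labels[iu[, 2]])
  to <- pmax(labels[iu[, 1]], labels[iu[, 2]])
  w <- S[iu]
  in_tree <- paste(from, to, sep = "\r") %in%
    paste(mst$edges$from, mst$edges$to, sep = "\r")
  cand <- which(!in_tree & w > floor)
  cand <- cand[order(-w[cand], from[cand], to[cand], method = "radix")]
  mst_report <- complexity_report(mst)
  edges <- mst$edges
  n <- length(labels)
  can_h <- n >= 3
  best_h <- if (can_h) h_index(mst) else -Inf
  best_k <- 0L
  if (can_h) {
    deg <- graph_degrees(mst)
    excess <- sum(pmax(deg - 2, 0))
    for (k in seq_along(cand)) {
      e <- cand[k]
      for (node in c(from[e], to[e])) {
        if (deg[node] >= 2) excess <- excess + 1L
        deg[node] <- deg[node] + 1L
      }
      h <- excess / (n - 2)
      if (h > best_h) { best_h <- h; best_k <- k }
    }
  }
  if (best_k > 0) {
    add <- cand[seq_len(best_k)]
    edges <- bind_rows(edges,
                       tibble(from = from[add], to = to[add],
                              weight = w[add]))
  }
  graph <- cm_graph(labels, edges, is_tree = best_k == 0 && mst$is_tree)
  structure(list(graph = graph, report = complexity_report(graph),
                 mst_report = mst_report,
                 n_candidates = length(cand), n_added = best_k,
                 floor = floor),
            class = "mrg_result")
}

#' @export
print.mrg_result <- function(x, ...) {
  cat(sprintf(
    "MRG: %d of %d candidate links re-added; H = %.3f (MST %.3f), E_G = %.3f\n",
    x$n_added, x$n_candidates, x$report$H, x$mst_report$H, x$report$E_G))
  invisible(x)
}

#' Stability-filtered MST (Meta-MST)
#'
#' Rebuilds the Auto-CM similarity matrix and its MST on `k` record
#' subsamples (each dropping a fraction of the records at random) and keeps
#' only the edges appearing in at least `support_threshold` of the `k`
#' trees. The result exposes the stable backbone of the map and may be
#' disconnected.
#'
#' @param indicators Indicator tibble (or 0/1 matrix) including any outcome
#'   columns that should appear as nodes.
#' @param k Number of resamples (default 10).
#' @param drop_fraction Fraction of records excluded per resample (default
#'   0.1).
#' @param support_threshold Minimum number of trees an edge must appear in
#'   (default 9).
#' @param seed Integer seed driving the resampling.
#' @param strata Optional vector (length = records); dropping is done
#'   proportionally within strata, protecting rare classes.
#' @param ... Auto-CM parameters passed to [train_autocm()].
#' @return A `"cm_graph"` whose edges carry `weight` (mean similarity over
#'   the supporting resamples) and `support` counts.
#' @export
meta_mst <- function(indicators, k = 10, drop_fraction = 0.1,
                     support_threshold = 9, seed = 1L, strata = NULL, ...) {
  X <- as.matrix(indicators)
  n <- nrow(X)
  stopifnot(k >= 1, drop_fraction >= 0, drop_fraction < 1,
            support_threshold >= 1, support_threshold <= k)
  labels <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  colnames(X) <- labels
  n_drop <- floor(drop_fraction * n)
  tally <- list()
  with_preserved_seed(seed, {
    for (r in seq_len(k)) {
      drop_idx <- draw_drop(n, n_drop, strata)
      Xr <- X[setdiff(seq_len(n), drop_idx), , drop = FALSE]
      model <- train_autocm(Xr, ...)
      tree <- minimum_spanning_tree(to_distances(similarity_matrix(model)))
      tally[[r]] <- tree$edges
    }
  })
  all_edges <- bind_rows(tally)
  supp <- all_edges %>%
    group_by(.data$from, .data$to) %>%
    summarise(support = dplyr::n(), weight = mean(.data$weight),
              .groups = "drop") %>%
    filter(.data$support >= support_threshold)
  g <- cm_graph(labels, supp[, c("from", "to", "weight", "support")],
                is_tree = FALSE)
  g$k <- k
  g$support_threshold <- support_threshold
  g
}

draw_drop <- function(n, n_drop, strata) {
  if (n_drop == 0) return(integer(0))
  if (is.null(strata)) return(sample.int(n, n_drop))
  idx_by <- split(seq_len(n), strata)
  per <- floor(n_drop * lengths(idx_by) / n)
  out <- unlist(lapply(seq_along(idx_by), function(i) {
    if (per[i] == 0) integer(0) else sample(idx_by[[i]], per[i])
  }), use.names = FALSE)
  short <- n_drop - length(out)
  if (short > 0) {
    out <- c(out, sample(setdiff(seq_len(n), out), short))
  }
  out
}

#' Rank nodes by connectivity
#'
#' @param g A `"cm_graph"`.
#' @param top_k Number of nodes to return (default all).
#' @return Tibble with `node` and `degree`, sorted by decreasing degree,
#'   ties by label.
#' @export
hub_nodes <- function(g, top_k = length(g$nodes)) {
  d <- graph_degrees(g)
  out <- tibble(node = names(d), degree = as.integer(d))
  out <- out[order(-out$degree, out$node, method = "radix"), ]
  head(out, top_k)
}

#' Per-group complexity contrast
#'
#' Runs the Auto-CM, MST and MRG separately on the case rows and the
#' control rows (outcome columns excluded: they are constant within a
#' group, as is any indicator that happens to have zero variance in that
#' group - such columns are dropped with a message) and contrasts the two
#' complexity reports. `delta` values are control minus case.
#'
#' @param indicators Indicator tibble from [expand_indicators()].
#' @param outcome Binary vector (1 = case); default: the cohort outcome
#'   stored on `indicators`.
#' @param floor MRG similarity floor (default 0.33).
#' @param min_rows Minimum rows per group (default 10).
#' @param ... Auto-CM parameters passed to [train_autocm()].
#' @return A list of class `"complexity_contrast"`: per-group `report`,
#'   `mst`, `mrg` and dropped-column lists, plus `delta` (`H`, `E_G`).
#' @export
group_complexity_contrast <- function(indicators, outcome = NULL,
                                      floor = 0.33, min_rows = 10, ...) {
  y <- outcome %||% attr(indicators, "outcome")
  info <- indicator_info(indicators)
  feat <- info$column[info$role == "feature"]
  X <- as.matrix(indicators[, feat, drop = FALSE])
  run_group <- function(rows, label) {
    if (length(rows) < min_rows) {
      abort(sprintf("Group '%s' has %d rows; need at least %d.",
                    label, length(rows), min_rows),
            class = "twistmap_error_graph")
    }
    Xg <- X[rows, , drop = FALSE]
    const <- apply(Xg, 2, function(x) max(x) == min(x))
    if (any(const)) {
      inform(sprintf("%s group: dropping %d constant column(s)",
                     label, sum(const)))
      Xg <- Xg[, !const, drop = FALSE]
    }
    model <- train_autocm(Xg, ...)
    S <- similarity_matrix(model)
    mst <- minimum_spanning_tree(to_distances(S))
    mrg <- maximally_regular_graph(S, mst, floor = floor)
    list(report = mrg$report, mst = mst, mrg = mrg,
         dropped = colnames(X)[const], n_rows = length(rows))
  }
  case <- run_group(which(y == 1), "case")
  control <- run_group(which(y == 0), "control")
  structure(list(case = case, control = control,
                 delta = list(H = control$report$H - case$report$H,
                              E_G = control$report$E_G - case$report$E_G)),
            class = "complexity_contrast")
}

#' @export
print.complexity_contrast <- function(x, ...) {
  cat(sprintf(
    paste0("Complexity contrast (MRG):\n",
           "  cases    (n=%3d): H = %.3f, E_G = %.3f\n",
           "  controls (n=%3d): H = %.3f, E_G = %.3f\n",
           "  delta (control - case): H = %+.3f, E_G = %+.3f\n"),
    x$case$n_rows, x$case$report$H, x$case$report$E_G,
    x$control$n_rows, x$control$report$H, x$control$report$E_G,
    x$delta$H, x$delta$E_G))
  invisible(x)
}

# Unique path between two nodes of a tree (BFS with parent pointers).
tree_path <- function(g, from, to) {
  stopifnot(from %in% g$nodes, to %in% g$nodes)
  adj <- split(c(g$edges$to, g$edges$from),
               factor(c(g$edges$from, g$edges$to), levels = g$nodes))
  parent <- setNames(rep(NA_character_, length(g$nodes)), g$nodes)
  seen <- setNames(logical(length(g$nodes)), g$nodes)
  queue <- from
  seen[from] <- TRUE
  while (length(queue) > 0 && !seen[to]) {
    u <- queue[1]; queue <- queue[-1]
    nb <- adj[[u]]
    new <- nb[!seen[nb]]
    parent[new] <- u
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  if (!seen[to]) return(character(0))
  path <- to
  while (path[1] != from) path <- c(parent[path[1]], path)
  unname(path)
}

# Nodes reachable from `from` after removing `blocked` from the graph.
reachable_without <- function(g, from, blocked) {
  keep <- setdiff(g$nodes, blocked)
  sub <- cm_graph(keep,
                  g$edges[g$edges$from %in% keep & g$edges$to %in% keep, ],
                  is_tree = FALSE)
  comp <- components_of(sub)
  names(comp)[comp == comp[from]]
}
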