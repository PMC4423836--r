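#' Tidy an indicator mask
#'
#' @param x A `"twist_mask"`.
#' @param ... Unused.
#' @return One row per feature column: `column`, `parent`, `category_label`,
#'   `selected`.
#' @export
tidy.twist_mask <- function(x, ...) {
  info <- x$info[x$info$role == "feature",
                 c("column", "parent", "category_label")]
  info$selected <- as.logical(x$bits[info$column])
  as_tibble(info)
}

#' @rdname tidy.twist_mask
#' @export
glance.twist_mask <- function(x, ...) {
  tibble(best_fitness = x$fitness, n_selected = x$n_selected,
         n_columns = x$n_columns,
         generations = nrow(x$trace), n_evaluations = x$n_evaluations)
}

#' Tidy a train/test split
#'
#' @param x A `"twist_split"`.
#' @param ... Unused.
#' @return One row per record: `row`, `set` ("train"/"test").
#' @export
tidy.twist_split <- function(x, ...) {
  tibble(row = seq_along(x$membership),
         set = ifelse(x$membership == 1L, "train", "test"))
}

#' @rdname tidy.twist_split
#' @export
glance.twist_split <- function(x, ...) {
  tibble(fitness = x$fitness, n_train = x$n_train, n_test = x$n_test,
         case_fraction_train = x$case_fraction_train,
         case_fraction_test = x$case_fraction_test)
}

#' Tidy an Auto-CM model into pairwise similarities
#'
#' @param x A trained `"autocm_model"`.
#' @param ... Unused.
#' @return One row per unordered variable pair: `var1`, `var2`,
#'   `similarity`, and its verbal `strength` (see [classify_strength()]).
#' @export
tidy.autocm_model <- function(x, ...) {
  S <- similarity_matrix(x)
  iu <- which(upper.tri(S), arr.ind = TRUE)
  out <- tibble(var1 = x$labels[iu[, 1]], var2 = x$labels[iu[, 2]],
                similarity = S[iu])
  out$strength <- classify_strength(out$similarity)
  arrange(out, desc(.data$similarity))
}

#' @rdname tidy.autocm_model
#' @export
glance.autocm_model <- function(x, ...) {
  tibble(n_variables = length(x$labels), C = x$C,
         epochs_run = x$epochs_run, converged = x$converged,
         final_signal = x$signal[length(x$signal)])
}

#' Tidy a graph into its edge list
#'
#' @param x A `"cm_graph"`.
#' @param ... Unused.
#' @return The edge tibble (`from`, `to`, `weight`, and `support` for
#'   Meta-MST graphs).
#' @export
tidy.cm_graph <- function(x, ...) x$edges

#' @rdname tidy.cm_graph
#' @export
glance.cm_graph <- function(x, ...) {
  r <- complexity_report(x)
  tibble(n_nodes = length(x$nodes), n_edges = r$A, H = r$H, E_G = r$E_G,
         pruning_cycles = r$P, is_tree = x$is_tree,
         connected = graph_is_connected(x))
}

#' @export
tidy.mrg_result <- function(x, ...) tidy(x$graph)

#' @export
glance.mrg_result <- function(x, ...) {
  g <- glance(x$graph)
  g$n_added <- x$n_added
  g$n_candidates <- x$n_candidates
  g
}

#' Tidy a per-group complexity contrast
#'
#' @param x A `"complexity_contrast"`.
#' @param ... Unused.
#' @return One row per group with `H`, `E_G`, arcs `A`, pruning cycles `P`.
#' @export
tidy.complexity_contrast <- function(x, ...) {
  bind_rows(lapply(c("case", "control"), function(gr) {
    r <- x[[gr]]$report
    tibble(group = gr, n_rows = x[[gr]]$n_rows,
           H = r$H, E_G = r$E_G, A = r$A, P = r$P)
  }))
}

#' @rdname tidy.complexity_contrast
#' @export
glance.complexity_contrast <- function(x, ...) {
  tibble(delta_H = x$delta$H, delta_E_G = x$delta$E_G)
}

#' @export
glance.complexity_report <- function(x, ...) {
  tibble(H = x$H, E_G = x$E_G, A = x$A, P = x$P)
}
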