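#' Train an Auto Contractive Map
#'
#' The Auto Contractive Map (Auto-CM) is a three-layer adaptive network with
#' as many units per layer as input variables. Each epoch presents every
#' record `x` (entries in `[0, 1]`) and lets the network contract its output
#' toward zero while the connection matrix `W` absorbs the co-activation
#' structure of the inputs:
#'
#' * hidden layer: `m_h[i] = x[i] * (1 - v[i]/C)`
#' * mono-connection update: `dv[i] = (x[i] - m_h[i]) * (1 - v[i]/C)`,
#'   averaged over records and applied first;
#' * with the updated `v`, `Net[i] = (1/C) * sum_j m_h[j] * W[j,i]`, output
#'   `m_t[i] = m_h[i] * (1 - Net[i]/C)`, and
#'   `dW[j,i] = (m_h[i] - m_t[i]) * (1 - W[j,i]/C) * m_h[j]`, averaged over
#'   records.
#'
#' Updates are accumulated per epoch (batch), so training is invariant to
#' record order and fully deterministic given the initial value. Every
#' `v[i]` grows monotonically toward the contraction parameter `C` and the
#' mean output signal shrinks; training stops when it falls below `tol` or
#' after `max_epochs`. The trained `W` is read as a variable-similarity
#' matrix via [similarity_matrix()].
#'
#' @param X Numeric matrix or data frame with entries in `[0, 1]` (typically
#'   a binary indicator matrix, including the `Event`/`No_Event` columns
#'   when mapping a whole cohort); at least 2 columns, and no constant
#'   column when there are 2 or more rows.
#' @param C Contraction parameter (> 1). The default (`NULL`) adapts to the
#'   data as `max(2, mean(rowSums(X)) * mean(X))`, one "co-activation unit":
#'   large enough that the weight dynamics stay bounded, small enough that
#'   strongly co-active pairs saturate towards `C` and the similarity
#'   matrix spans the unit scale on which the verbal strength bands (see
#'   [classify_strength()]) are read. Larger values (e.g. `C = ncol(X)`)
#'   give a tamer, strictly contractive regime whose similarities keep the
#'   same ranking on a compressed scale.
#' @param max_epochs Epoch cap (default 1000).
#' @param tol Stop when the mean output signal falls below this (default
#'   1e-6).
#' @param init_eps Uniform initial value of `v` and `W` (default 0.01; zero
#'   initialisation provably stalls the dynamics).
#' @param track_v Record the per-epoch `v` trajectory in the returned
#'   model's `v_history` (rows = epochs); default `FALSE`.
#' @return An object of class `"autocm_model"` with fields `C`, `v`, `W`,
#'   `labels`, `epochs_run`, `converged`, and the per-epoch `signal` trace.
#' @export
train_autocm <- function(X, C = NULL, max_epochs = 1000, tol = 1e-6,
                         init_eps = 0.01, track_v = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) < 2) {
    abort("Auto-CM needs at least 2 columns.", class = "twistmap_error_autocm")
  }
  if (anyNA(X) || min(X) < 0 || max(X) > 1) {
    abort("Auto-CM input must be complete with entries in [0, 1].",
          class = "twistmap_error_autocm")
  }
  if (nrow(X) >= 2) {
    const <- which(apply(X, 2, function(x) max(x) == min(x)))
    if (length(const) > 0) {
      abort(paste0("Constant column(s) must be dropped before Auto-CM: ",
                   paste(colnames(X)[const] %||% const, collapse = ", ")),
            class = "twistmap_error_autocm")
    }
  }
  p <- ncol(X)
  C <- C %||% max(2, mean(rowSums(X)) * mean(X))
  stopifnot(C > 1)
  n <- nrow(X)
  v <- rep(init_eps, p)
  W <- matrix(init_eps, p, p)
  signal <- numeric(max_epochs)
  vh <- if (track_v) matrix(NA_real_, max_epochs, p) else NULL
  epochs <- 0L
  converged <- FALSE
  for (e in seq_len(max_epochs)) {
    Mh <- X * rep(1 - v / C, each = n)
    v <- v + colSums(X - Mh) / n * (1 - v / C)
    Mh <- X * rep(1 - v / C, each = n)
    Net <- (Mh %*% W) / C
    Mt <- Mh * (1 - Net / C)
    W <- W + crossprod(Mh, Mh - Mt) * (1 - W / C) / n
    epochs <- e
    if (track_v) vh[e, ] <- v
    signal[e] <- mean(Mt)
    if (signal[e] < tol) { converged <- TRUE; break }
  }
  structure(list(C = C, v = v, W = W,
                 labels = colnames(X) %||% paste0("V", seq_len(p)),
                 epochs_run = epochs, converged = converged,
                 signal = signal[seq_len(epochs)],
                 v_history = if (track_v) vh[seq_len(epochs), , drop = FALSE]),
            class = "autocm_model")
}

#' Read the trained connection matrix as a similarity matrix
#'
#' Symmetrises and rescales the Auto-CM connection weights to the unit
#' interval: `S[i,j] = (W[i,j] + W[j,i]) / (2C)`, clipped to `[0, 1]`, with
#' unit diagonal. Entries measure the degree of membership of the two
#' indicator variables in the same fuzzy set; only positive association is
#' represented.
#'
#' @param model A trained `"autocm_model"`.
#' @return A symmetric numeric matrix in `[0, 1]` with the model's labels as
#'   dimnames, of class `"autocm_similarity"`.
#' @export
similarity_matrix <- function(model) {
  if (!inherits(model, "autocm_model")) {
    abort("similarity_matrix() expects a trained autocm_model.",
          class = "twistmap_error_autocm")
  }
  S <- (model$W + t(model$W)) / (2 * model$C)
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 1
  dimnames(S) <- list(model$labels, model$labels)
  class(S) <- c("autocm_similarity", class(S))
  S
}

#' Turn similarities into distances
#'
#' `D = 1 - S`; minimising total distance over spanning trees is the same
#' as maximising total similarity, so the minimum spanning tree of `D`
#' keeps the strongest associations.
#'
#' @param S Similarity matrix in `[0, 1]`.
#' @return Distance matrix `1 - S` with zero diagonal.
#' @export
to_distances <- function(S) {
  D <- 1 - unclass(S)
  diag(D) <- 0
  D
}

#' Verbal strength category of a similarity weight
#'
#' Classifies a trained connection weight `w` on the conventional scale:
#' null or very low for `w <= 0.33`, quite low for `0.33 < w <= 0.66`,
#' quite high for `0.66 < w <= 0.84`, very high for `w > 0.84`.
#'
#' @param w Numeric vector of similarity values in `[0, 1]`.
#' @return Factor with levels `null/very-low`, `quite-low`, `quite-high`,
#'   `very-high`.
#' @examples
#' classify_strength(c(0.2, 0.5, 0.7, 0.9))
#' @export
classify_strength <- function(w) {
  if (anyNA(w) || any(w < 0) || any(w > 1)) {
    abort("Similarity values must lie in [0, 1].",
          class = "twistmap_error_autocm")
  }
  lv <- c("null/very-low", "quite-low", "quite-high", "very-high")
  cut(w, breaks = c(-Inf, 0.33, 0.66, 0.84, Inf), labels = lv)
}

#' Write an Auto-CM model as JSON
#'
#' @param model A trained `"autocm_model"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_autocm <- function(model, path) {
  jsonlite::write_json(
    list(C = model$C, v = model$v, W = model$W, labels = model$labels,
         epochs_run = model$epochs_run, converged = model$converged),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @export
print.autocm_model <- function(x, ...) {
  cat(sprintf(
    "Auto-CM model: %d variables, C = %.3g, %d epoch%s (%sconverged)\n",
    length(x$labels), x$C, x$epochs_run,
    if (x$epochs_run == 1) "" else "s", if (x$converged) "" else "not "))
  invisible(x)
}
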