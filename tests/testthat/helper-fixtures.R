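# Shared fixtures and independent oracles, built in code at test time.

toy_schema <- function() {
  cohort_schema(c("bmi", "rs0001", "smoking"),
                c("continuous", "genotype3", "binary"))
}

toy_cohort <- function(n = 30, seed = 1) {
  withr::with_seed(seed, {
    ch <- tibble::tibble(
      bmi = rnorm(n, 26, 3),
      rs0001 = sample(0:2, n, replace = TRUE),
      smoking = rbinom(n, 1, 0.3),
      outcome = rbinom(n, 1, 0.4)
    )
    attr(ch, "schema") <- toy_schema()
    ch
  })
}

# Random binary matrix without constant columns.
random_binary <- function(n, p, prob = 0.5, seed = NULL) {
  draw <- function() {
    X <- matrix(rbinom(n * p, 1, prob), n, p)
    while (any(apply(X, 2, function(x) max(x) == min(x)))) {
      X <- matrix(rbinom(n * p, 1, prob), n, p)
    }
    colnames(X) <- sprintf("c%02d", seq_len(p))
    X
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Exhaustive minimum-spanning-tree weight by enumerating every labelled
# tree through its Prufer sequence (vectorised decode across sequences).
# Independent of the package's Kruskal implementation.
prufer_min_spanning_weight <- function(D) {
  n <- nrow(D)
  stopifnot(n >= 2, n <= 8)
  if (n == 2) return(D[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  S <- nrow(seqs)
  deg <- matrix(1L, S, n)
  for (k in seq_len(n - 2)) {
    idx <- cbind(seq_len(S), seqs[, k])
    deg[idx] <- deg[idx] + 1L
  }
  total <- numeric(S)
  for (k in seq_len(n - 2)) {
    leaf <- max.col(deg == 1L, ties.method = "first")
    total <- total + D[cbind(leaf, seqs[, k])]
    deg[cbind(seq_len(S), leaf)] <- 0L
    idx <- cbind(seq_len(S), seqs[, k])
    deg[idx] <- deg[idx] - 1L
  }
  a <- max.col(deg == 1L, ties.method = "first")
  deg[cbind(seq_len(S), a)] <- 0L
  b <- max.col(deg == 1L, ties.method = "first")
  min(total + D[cbind(a, b)])
}

random_distance_matrix <- function(n) {
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- runif(n * (n - 1) / 2)
  D <- D + t(D)
  rownames(D) <- colnames(D) <- sprintf("n%02d", seq_len(n))
  D
}

# Graph builders for closed-form complexity checks.
path_graph <- function(n) {
  lab <- sprintf("p%02d", seq_len(n))
  cm_graph(lab, tibble::tibble(from = lab[-n], to = lab[-1],
                               weight = 0.5), is_tree = TRUE)
}

star_graph <- function(n) {
  lab <- sprintf("s%02d", seq_len(n))
  cm_graph(lab, tibble::tibble(from = lab[1], to = lab[-1],
                               weight = 0.5), is_tree = TRUE)
}

cycle_graph <- function(n) {
  lab <- sprintf("c%02d", seq_len(n))
  cm_graph(lab, tibble::tibble(from = lab, to = lab[c(2:n, 1)],
                               weight = 0.5), is_tree = FALSE)
}

# Small continuous cohort for resampling-stability tests.
random_continuous_cohort <- function(n = 60, n_vars = 4, rho = 0.5,
                                     seed = 1) {
  generate_contrast_cohort(n_cases = ceiling(n / 2),
                           n_controls = floor(n / 2),
                           n_vars = n_vars, rho_cases = rho,
                           rho_controls = rho, seed = seed)
}
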