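test_that("minimum_spanning_tree solves small instances exactly", {
  D <- matrix(c(0, 0.1, 0.5,
                0.1, 0, 0.2,
                0.5, 0.2, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  g <- minimum_spanning_tree(D)
  expect_true(g$is_tree)
  expect_equal(nrow(g$edges), 2)
  expect_setequal(paste(g$edges$from, g$edges$to), c("a b", "b c"))
  expect_equal(sum(1 - g$edges$weight), 0.3)
})

test_that("MST matches exhaustive enumeration and igraph on random instances", {
  withr::with_seed(11, {
    for (i in 1:15) {
      n <- sample(3:7, 1)
      D <- random_distance_matrix(n)
      g <- minimum_spanning_tree(D)
      expect_equal(nrow(g$edges), n - 1)
      total <- sum(1 - g$edges$weight)
      expect_equal(total, prufer_min_spanning_weight(D), tolerance = 1e-12)
      ig <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                                weighted = TRUE)
      expect_equal(total,
                   sum(igraph::E(igraph::mst(ig))$weight),
                   tolerance = 1e-12)
    }
  })
})

test_that("equal distances yield the lexicographically first spanning tree", {
  n <- 5
  D <- matrix(0.4, n, n); diag(D) <- 0
  lab <- c("a", "b", "c", "d", "e")
  dimnames(D) <- list(lab, lab)
  g <- minimum_spanning_tree(D)
  # first edges in lexicographic pair order: a-b, a-c, a-d, a-e
  expect_equal(g$edges$from, rep("a", 4))
  expect_equal(g$edges$to, c("b", "c", "d", "e"))
})

test_that("hubness H has the stated closed forms and bounds", {
  expect_equal(h_index(path_graph(5)), 0)
  for (n in c(4, 6, 10)) {
    expect_equal(h_index(star_graph(n)), (n - 3) / (n - 2))
  }
  # tree with degree sequence (3,3,1,1,1,1):  H = 2/4
  g <- cm_graph(letters[1:6],
                tibble::tibble(from = c("a", "a", "a", "b", "b"),
                               to = c("b", "c", "d", "e", "f"),
                               weight = 0.5), is_tree = TRUE)
  expect_equal(h_index(g), 0.5)
  expect_error(h_index(cm_graph(c("a", "b"),
                                tibble::tibble(from = "a", to = "b",
                                               weight = 1))),
               class = "twistmap_error_graph")
  # H never decreases when an edge lands on a node of degree >= 2
  g2 <- cm_graph(g$nodes, dplyr::bind_rows(
    g$edges, tibble::tibble(from = "a", to = "e", weight = 0.5)))
  expect_gte(h_index(g2), h_index(g))
})

test_that("pruning cycles count deletion waves", {
  expect_equal(pruning_cycles(path_graph(4)), 2)
  expect_equal(pruning_cycles(star_graph(6)), 2)
  expect_equal(pruning_cycles(cycle_graph(3)), 1)
  expect_equal(pruning_cycles(path_graph(2)), 1)
  expect_equal(pruning_cycles(cycle_graph(6)), 1)
})

test_that("topological entropy combines arcs, pruning and degree information", {
  # star on 4: A=3, P=2, H_S hand-computed from degrees (3,1,1,1)
  hs <- -(0.5 * log2(0.5) + 3 * (1 / 6) * log2(1 / 6))
  expect_equal(topological_entropy(star_graph(4)), 1.5 * hs,
               tolerance = 1e-12)
  expect_equal(topological_entropy(path_graph(2)), 1)
  # adding an edge that leaves P unchanged strictly increases A/P
  s6 <- star_graph(6)
  s6_plus <- cm_graph(s6$nodes, dplyr::bind_rows(
    s6$edges, tibble::tibble(from = "s02", to = "s03", weight = 0.5)))
  expect_equal(pruning_cycles(s6_plus), pruning_cycles(s6))
  expect_gt(nrow(s6_plus$edges) / pruning_cycles(s6_plus),
            nrow(s6$edges) / pruning_cycles(s6))
})

test_that("the MRG re-adds strong links and contains the MST", {
  withr::with_seed(12, {
    X <- random_binary(80, 9)
    X[, 2] <- X[, 1]; X[, 3] <- ifelse(runif(80) < 0.9, X[, 1], 1 - X[, 1])
    colnames(X) <- sprintf("c%d", 1:9)
    m <- train_autocm(X)
    S <- similarity_matrix(m)
    mst <- minimum_spanning_tree(to_distances(S))
    mrg <- maximally_regular_graph(S, mst)
    # MST is a subgraph of the MRG
    key <- function(g) paste(g$edges$from, g$edges$to)
    expect_true(all(key(mst) %in% key(mrg$graph)))
    expect_gte(mrg$report$H, mrg$mst_report$H)
    expect_gte(mrg$report$A, mrg$mst_report$A)
  })
})

test_that("MRG with no candidate above the floor equals the MST", {
  S <- matrix(0.1, 4, 4); diag(S) <- 1
  S[1, 2] <- S[2, 1] <- 0.9
  S[2, 3] <- S[3, 2] <- 0.8
  S[3, 4] <- S[4, 3] <- 0.7
  dimnames(S) <- list(letters[1:4], letters[1:4])
  mst <- minimum_spanning_tree(to_distances(S))
  mrg <- maximally_regular_graph(S, mst, floor = 0.33)
  expect_equal(mrg$n_added, 0)
  expect_identical(mrg$graph$edges, mst$edges)
  expect_equal(glance(mrg$graph), glance(mst))
})

test_that("a leaf-closing link leaves H unchanged but raises the arc count", {
  # star at b plus a strong a-c link: the link closes the triangle a-b-c,
  # its endpoints only reach degree 2, so H is unchanged while A increments
  S <- matrix(0.05, 4, 4); diag(S) <- 1
  S[1, 2] <- S[2, 1] <- 0.9    # a-b
  S[2, 3] <- S[3, 2] <- 0.85   # b-c
  S[2, 4] <- S[4, 2] <- 0.8    # b-d
  S[1, 3] <- S[3, 1] <- 0.6    # a-c candidate
  dimnames(S) <- list(letters[1:4], letters[1:4])
  mst <- minimum_spanning_tree(to_distances(S))
  with_edge <- cm_graph(mst$nodes, dplyr::bind_rows(
    mst$edges, tibble::tibble(from = "a", to = "c", weight = 0.6)))
  expect_equal(h_index(with_edge), h_index(mst))
  expect_equal(nrow(with_edge$edges), nrow(mst$edges) + 1)
  # since H cannot rise, the MRG search keeps the earliest (tree) graph
  mrg <- maximally_regular_graph(S, mst, floor = 0.33)
  expect_equal(mrg$n_candidates, 1)
  expect_equal(mrg$report$H, mrg$mst_report$H)
  expect_equal(mrg$n_added, 0)
})

test_that("planted duplicate blocks create cycles in the MRG", {
  withr::with_seed(13, {
    base <- random_binary(100, 4)
    X <- cbind(base[, 1], base[, 1], base[, 1],
               base[, 2], base[, 2], base[, 2], base[, 3:4])
    colnames(X) <- sprintf("c%d", 1:8)
    m <- train_autocm(X)
    S <- similarity_matrix(m)
    mrg <- maximally_regular_graph(S, floor = 0.33)
    # cycles exist: more arcs than a tree can carry
    expect_gt(mrg$report$A, length(mrg$graph$nodes) - 1)
    expect_gte(mrg$report$P, 2)
  })
})

test_that("meta_mst with no dropping reproduces the MST exactly", {
  ch <- random_continuous_cohort(n = 40, seed = 14)
  ind <- expand_indicators(ch, include_outcome = FALSE)
  X <- as.matrix(ind)
  mst <- minimum_spanning_tree(to_distances(similarity_matrix(
    train_autocm(X))))
  meta <- meta_mst(ind, k = 10, drop_fraction = 0, support_threshold = 10,
                   seed = 15)
  expect_equal(meta$edges$from, mst$edges$from)
  expect_equal(meta$edges$to, mst$edges$to)
  expect_equal(meta$edges$weight, mst$edges$weight, tolerance = 1e-12)
  expect_true(all(meta$edges$support == 10))
})

test_that("meta_mst support thresholds are nested", {
  ch <- random_continuous_cohort(n = 50, seed = 16)
  ind <- expand_indicators(ch, include_outcome = FALSE)
  g10 <- meta_mst(ind, k = 10, support_threshold = 10, seed = 17)
  g9 <- meta_mst(ind, k = 10, support_threshold = 9, seed = 17)
  key <- function(g) paste(g$edges$from, g$edges$to)
  expect_true(all(key(g10) %in% key(g9)))
  expect_lte(nrow(g10$edges), nrow(g9$edges))
  # every surviving edge appeared in at least that many resample MSTs
  expect_true(all(g9$edges$support >= 9))
})

test_that("strongly structured blocks survive resampling at full support", {
  withr::with_seed(18, {
    base <- matrix(rbinom(120 * 3, 1, 0.5), 120, 3)
    X <- cbind(base[, 1], base[, 1], base[, 2], base[, 2],
               matrix(rbinom(120 * 4, 1, 0.5), 120, 4))
    colnames(X) <- sprintf("c%d", 1:8)
    meta <- meta_mst(tibble::as_tibble(X), k = 10, drop_fraction = 0.1,
                     support_threshold = 10, seed = 19)
    key <- paste(meta$edges$from, meta$edges$to)
    expect_true(all(c("c1 c2", "c3 c4") %in% key))
  })
})

test_that("hub_nodes ranks by degree with label tie-breaks", {
  expect_equal(hub_nodes(star_graph(6), 1)$node, "s01")
  expect_equal(hub_nodes(star_graph(6), 1)$degree, 5L)
  hp <- hub_nodes(path_graph(4))
  expect_equal(hp$node, c("p02", "p03", "p01", "p04"))
})

test_that("group contrast is zero for row-identical groups", {
  ch <- random_continuous_cohort(n = 40, seed = 20)
  ind0 <- expand_indicators(ch, include_outcome = FALSE)
  X <- dplyr::bind_rows(ind0, ind0)
  attr(X, "indicator_info") <- indicator_info(ind0)
  attr(X, "outcome") <- rep(c(1L, 0L), each = nrow(ind0))
  cc <- group_complexity_contrast(X)
  expect_equal(cc$delta$H, 0)
  expect_equal(cc$delta$E_G, 0)
  expect_equal(cc$case$report$A, cc$control$report$A)
  # the report carries arcs, pruning cycles and degree histograms
  for (gr in c("case", "control")) {
    r <- cc[[gr]]$report
    expect_true(all(c("H", "E_G", "A", "P", "degree_histogram") %in%
                      names(r)))
    expect_s3_class(r$degree_histogram, "tbl_df")
  }
})

test_that("graph exports round-trip through igraph formats", {
  g <- star_graph(5)
  dir <- withr::local_tempdir()
  write_graphml(g, file.path(dir, "g.graphml"))
  back <- igraph::read_graph(file.path(dir, "g.graphml"),
                             format = "graphml")
  expect_equal(igraph::gorder(back), 5)
  expect_equal(igraph::gsize(back), 4)
  write_dot(g, file.path(dir, "g.dot"))
  expect_true(any(grepl("--", readLines(file.path(dir, "g.dot")))))
  write_edge_list(g, file.path(dir, "g.csv"))
  expect_equal(nrow(readr::read_csv(file.path(dir, "g.csv"),
                                    show_col_types = FALSE)), 4)
})
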