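test_that("one epoch on a single record reproduces the hand-derived update", {
  # independent scalar evaluation of the update equations
  C <- 2; eps <- 0.01
  mh <- 1 * (1 - eps / C)
  dv <- (1 - mh) * (1 - eps / C)
  v1 <- eps + dv
  mh2 <- 1 * (1 - v1 / C)
  net <- (mh2 * eps + mh2 * eps) / C
  mt <- mh2 * (1 - net / C)
  dw <- (mh2 - mt) * (1 - eps / C) * mh2

  model <- train_autocm(matrix(c(1, 1), nrow = 1), C = 2, max_epochs = 1,
                        init_eps = eps)
  expect_lt(max(abs(model$v - eps - dv)), 1e-12)
  expect_lt(max(abs(model$W[1, 2] - eps - dw)), 1e-12)
  expect_lt(max(abs(model$W[2, 1] - eps - dw)), 1e-12)
  # the derived magnitudes themselves
  expect_equal(dv, 0.004975, tolerance = 1e-6)
  expect_equal(dw, 0.00487, tolerance = 1e-2)
})

test_that("mono-connections grow monotonically to C and signal contracts", {
  withr::with_seed(2, {
    for (i in 1:5) {
      X <- random_binary(sample(30:100, 1), sample(5:12, 1))
      # v is monotone and bounded at any C, including the adaptive default
      m <- train_autocm(X, track_v = TRUE)
      expect_true(all(diff(m$v_history) >= -1e-12))
      expect_true(all(m$v_history <= m$C + 1e-9))
      # in the strictly contractive regime the signal is also monotone
      m2 <- train_autocm(X, C = ncol(X))
      expect_true(all(diff(m2$signal) <= 1e-9))
    }
  })
})

test_that("training is invariant to record order", {
  X <- random_binary(50, 8, seed = 3)
  m1 <- train_autocm(X)
  m2 <- train_autocm(X[sample(nrow(X)), ])
  expect_equal(m1$W, m2$W, tolerance = 1e-12)
  expect_equal(m1$v, m2$v, tolerance = 1e-12)
})

test_that("similarity ranking tracks pairwise co-occurrence", {
  # brute-force oracle: count of records where both columns are active
  withr::with_seed(4, {
    rho <- vapply(1:10, function(i) {
      X <- random_binary(100, 10)
      m <- train_autocm(X)
      S <- similarity_matrix(m)
      co <- crossprod(X)
      cor(S[upper.tri(S)], co[upper.tri(co)], method = "spearman")
    }, numeric(1))
    expect_true(all(rho > 0.5))
  })
})

test_that("duplicated columns attain the top off-diagonal similarity", {
  withr::with_seed(5, {
    for (i in 1:5) {
      X <- random_binary(80, 8)
      X <- cbind(X, dup = X[, 1])
      m <- train_autocm(X)
      S <- similarity_matrix(m)
      diag(S) <- NA
      expect_gte(S[1, 9], max(S, na.rm = TRUE) - 1e-12)
    }
  })
})

test_that("similarity ranking is stable across the contraction parameter", {
  withr::with_seed(6, {
    for (i in 1:5) {
      X <- random_binary(80, 10)
      s1 <- similarity_matrix(train_autocm(X))
      s2 <- similarity_matrix(train_autocm(X, C = ncol(X)))
      rho <- cor(s1[upper.tri(s1)], s2[upper.tri(s2)], method = "spearman")
      expect_gt(rho, 0.5)
    }
  })
})

test_that("similarity matrix is symmetric, bounded, and inverts to distance", {
  X <- random_binary(60, 7, seed = 7)
  m <- train_autocm(X)
  S <- similarity_matrix(m)
  expect_true(isSymmetric(unclass(unname(S))))
  expect_true(all(S >= 0 & S <= 1))
  expect_equal(unname(diag(S)), rep(1, 7))
  D <- to_distances(S)
  expect_equal(unname(diag(D)), rep(0, 7))
  s <- S[upper.tri(S)]; d <- D[upper.tri(D)]
  expect_equal(order(d), rev(order(s)))   # exact rank reversal
  # algebraic bounds of the W -> S map
  m2 <- m
  m2$W <- matrix(m$C, 3, 3); m2$labels <- letters[1:3]
  expect_equal(unname(similarity_matrix(m2)[1, 2]), 1)
  m2$W <- matrix(0, 3, 3)
  expect_equal(unname(similarity_matrix(m2)[1, 2]), 0)
  m2$W <- matrix(c(0, 0.4, 0, 0.6, 0, 0, 0, 0, 0), 3, 3)
  m2$C <- 1
  expect_equal(unname(similarity_matrix(m2)[1, 2]), 0.5)
})

test_that("strength bands follow the published cut-points", {
  expect_equal(as.character(classify_strength(0.20)), "null/very-low")
  expect_equal(as.character(classify_strength(0.33)), "null/very-low")
  expect_equal(as.character(classify_strength(0.50)), "quite-low")
  expect_equal(as.character(classify_strength(0.66)), "quite-low")
  expect_equal(as.character(classify_strength(0.70)), "quite-high")
  expect_equal(as.character(classify_strength(0.84)), "quite-high")
  expect_equal(as.character(classify_strength(0.8401)), "very-high")
  expect_error(classify_strength(1.2), class = "twistmap_error_autocm")
})

test_that("degenerate inputs are rejected with instructive errors", {
  X <- random_binary(20, 4, seed = 8)
  Xc <- cbind(X, const = 1L)
  expect_error(train_autocm(Xc), "const",
               class = "twistmap_error_autocm")
  expect_error(train_autocm(X - 2), class = "twistmap_error_autocm")
  expect_error(train_autocm(X[, 1, drop = FALSE]),
               class = "twistmap_error_autocm")
  expect_error(similarity_matrix(list(W = diag(2))),
               class = "twistmap_error_autocm")
})
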