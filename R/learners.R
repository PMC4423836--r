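#' Fit one learner of the TWIST bank
#'
#' The bank implements four classifiers from their defining computations,
#' each on binary indicator features: naive Bayes with Laplace smoothing,
#' logistic regression by gradient ascent, k-nearest neighbours under
#' Hamming distance, and a one-hidden-layer sigmoid network trained by
#' backpropagation. All return a model whose [predict()] method maps a new
#' 0/1 matrix to 0/1 class predictions.
#'
#' @param method One of `"naive_bayes"`, `"logistic"`, `"knn"`, `"mlp"`.
#' @param X Numeric 0/1 matrix (rows = individuals).
#' @param y Binary outcome vector; both classes must be present.
#' @param ... Hyperparameters: `alpha` (Laplace count, naive Bayes, default
#'   1), `lr`/`iters`/`lambda` (logistic), `k` (knn, default 5),
#'   `hidden`/`epochs`/`lr` (mlp).
#' @return An object of class `c("twist_<kind>", "twist_learner")`.
#' @export
fit_learner <- function(method, X, y, ...) {
  method <- match.arg(method, c("naive_bayes", "logistic", "knn", "mlp"))
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) < 2 || length(unique(y)) < 2) {
    abort("Learner fitting needs >= 2 rows with both classes present.",
          class = "twistmap_error_learner")
  }
  fit <- switch(method,
    naive_bayes = fit_naive_bayes(X, y, ...),
    logistic    = fit_logistic(X, y, ...),
    knn         = fit_knn(X, y, ...),
    mlp         = fit_mlp(X, y, ...)
  )
  class(fit) <- c(paste0("twist_", method), "twist_learner")
  fit
}

#' @export
predict.twist_learner <- function(object, newdata, ...) {
  object$predict(as.matrix(newdata))
}

# Naive Bayes on binary features, Laplace-smoothed counts.
fit_naive_bayes <- function(X, y, alpha = 1) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  p1 <- (colSums(X[y == 1, , drop = FALSE]) + alpha) / (n1 + 2 * alpha)
  p0 <- (colSums(X[y == 0, , drop = FALSE]) + alpha) / (n0 + 2 * alpha)
  # log-odds decomposition: score(x) = x . a + const
  a <- log(p1 / (1 - p1)) - log(p0 / (1 - p0))
  const <- sum(log(1 - p1) - log(1 - p0)) + log(n1 / n0)
  list(p1 = p1, p0 = p0, a = a, const = const,
       predict = function(Xn) {
         as.integer(drop(Xn %*% a) + const >= 0)
       })
}

# Logistic regression by full-batch gradient ascent with a small L2 ridge
# (keeps separable problems finite).
fit_logistic <- function(X, y, lr = NULL, iters = 500, lambda = 1e-4) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  if (is.null(lr)) lr <- 4 / p
  beta <- numeric(p)
  n <- nrow(X1)
  for (i in seq_len(iters)) {
    eta <- drop(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    beta <- beta + lr * (drop(crossprod(X1, y - mu)) / n - lambda * beta)
  }
  list(beta = beta,
       predict = function(Xn) {
         as.integer(drop(cbind(1, Xn) %*% beta) >= 0)
       })
}

# k-nearest neighbours under Hamming distance; distance ties resolved by
# training-row order, vote ties by the nearest neighbour's class.
fit_knn <- function(X, y, k = 5) {
  k <- min(k, nrow(X))
  list(X = X, y = y, k = k,
       predict = function(Xn) {
         D <- Xn %*% t(1 - X) + (1 - Xn) %*% t(X)   # Hamming counts
         apply_rows_int(D, function(d) {
           o <- order(d)[seq_len(k)]
           v <- mean(y[o])
           if (v > 0.5) 1L else if (v < 0.5) 0L else y[o[1]]
         })
       })
}

apply_rows_int <- function(M, f) {
  vapply(seq_len(nrow(M)), function(i) f(M[i, ]), integer(1))
}

# One hidden layer of sigmoid units, logistic output, full-batch
# backpropagation. Weight initialisation draws from the current RNG stream,
# so results are reproducible under the caller's seed.
fit_mlp <- function(X, y, hidden = 8, epochs = 300, lr = 0.5) {
  p <- ncol(X); n <- nrow(X)
  W1 <- matrix(runif((p + 1) * hidden, -0.5, 0.5), p + 1, hidden)
  W2 <- runif(hidden + 1, -0.5, 0.5)
  sig <- function(z) 1 / (1 + exp(-z))
  X1 <- cbind(1, X)
  for (e in seq_len(epochs)) {
    H <- sig(X1 %*% W1)          # n x hidden
    H1 <- cbind(1, H)
    out <- sig(drop(H1 %*% W2))
    d_out <- out - y             # dL/d eta_out (cross-entropy)
    gW2 <- drop(crossprod(H1, d_out)) / n
    d_hid <- (outer(d_out, W2[-1]) * H * (1 - H))
    gW1 <- crossprod(X1, d_hid) / n
    W2 <- W2 - lr * gW2
    W1 <- W1 - lr * gW1
  }
  list(W1 = W1, W2 = W2,
       predict = function(Xn) {
         H1 <- cbind(1, sig(cbind(1, Xn) %*% W1))
         as.integer(sig(drop(H1 %*% W2)) >= 0.5)
       })
}

#' Classification cost from predicted and observed classes
#'
#' The cost minimised by the TWIST selection loop: by default the
#' misclassification rate of the confusion matrix (1 - accuracy); root mean
#' square error is selectable as an alternative cost.
#'
#' @param pred,obs Binary 0/1 vectors of equal length.
#' @param cost `"misclassification"` (default) or `"rmse"`.
#' @return Cost in `[0, 1]`.
#' @examples
#' confusion_cost(c(1, 1, 0, 0), c(1, 0, 0, 0))  # 0.25
#' @export
confusion_cost <- function(pred, obs, cost = c("misclassification", "rmse")) {
  cost <- match.arg(cost)
  if (length(pred) != length(obs)) {
    abort("pred and obs must have equal length.",
          class = "twistmap_error_learner")
  }
  err <- mean((pred - obs)^2)
  if (cost == "rmse") sqrt(err) else err
}

#' Configure the learner bank
#'
#' The TWIST fitness is a held-out classification score averaged over the
#' enabled learners. The bank is pluggable; any nonempty subset of the four
#' implemented learners can be enabled, and per-learner hyperparameters are
#' passed through to [fit_learner()].
#'
#' @param enabled Character vector of learner kinds (default: all four).
#' @param params Named list of per-learner hyperparameter lists, e.g.
#'   `list(knn = list(k = 7))`.
#' @return An object of class `"learner_bank"`.
#' @export
learner_bank <- function(enabled = c("naive_bayes", "logistic", "knn", "mlp"),
                         params = list()) {
  enabled <- match.arg(enabled, c("naive_bayes", "logistic", "knn", "mlp"),
                       several.ok = TRUE)
  if (length(enabled) == 0) {
    abort("Learner bank must be nonempty.", class = "twistmap_error_learner")
  }
  structure(list(enabled = enabled, params = params),
            class = "learner_bank")
}

# Mean held-out accuracy over the bank for given train/test matrices.
bank_accuracy <- function(bank, Xtr, ytr, Xte, yte, cost = "misclassification") {
  accs <- vapply(bank$enabled, function(method) {
    fit <- do.call(fit_learner,
                   c(list(method = method, X = Xtr, y = ytr),
                     bank$params[[method]] %||% list()))
    1 - confusion_cost(predict(fit, Xte), yte, cost = cost)
  }, numeric(1))
  mean(accs)
}
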