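#' Configure the evolutionary search
#'
#' Settings of the genetic algorithm used for both TWIST stages (train/test
#' split optimisation and indicator-mask selection). The search keeps an
#' elite, selects parents by tournament with a nonzero chance of keeping the
#' weaker contestant, applies uniform crossover and per-bit mutation, and
#' each generation replaces part of the population with random immigrant
#' candidates ("doping"), injecting instability that guards against
#' premature convergence to a local optimum.
#'
#' @param population_size Number of candidate vectors (default 100).
#' @param generations Number of generations (default 500).
#' @param crossover_rate Probability of uniform crossover (default 0.9).
#' @param mutation_rate Per-bit flip probability; default `NULL` means `1/L`
#'   for vectors of length `L`.
#' @param immigrant_fraction Fraction of each generation replaced by random
#'   immigrants (default 0.1).
#' @param elitism Number of best candidates copied unchanged (default 2).
#' @param tournament_p Probability that the fitter tournament contestant is
#'   selected (default 0.75; the rest keeps sub-optimal parents in play).
#' @param seed Integer seed for the whole run.
#' @return An object of class `"ga_config"`.
#' @export
ga_config <- function(population_size = 100, generations = 500,
                      crossover_rate = 0.9, mutation_rate = NULL,
                      immigrant_fraction = 0.1, elitism = 2,
                      tournament_p = 0.75, seed = 1L) {
  stopifnot(population_size >= 1, generations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            is.null(mutation_rate) ||
              (mutation_rate >= 0 && mutation_rate <= 1),
            immigrant_fraction >= 0, immigrant_fraction <= 1,
            elitism >= 0, elitism < population_size ||
              (elitism == 0 && population_size >= 1))
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 immigrant_fraction = immigrant_fraction,
                 elitism = as.integer(min(elitism, population_size - 1)),
                 tournament_p = tournament_p,
                 seed = as.integer(seed)),
            class = "ga_config")
}

# Generic GA engine over binary vectors.
#  evaluate: function(matrix of candidates) -> numeric fitness vector
#  random_candidate: function() -> binary vector
#  repair: function(bits) -> bits (feasibility fix-up)
run_ga <- function(L, evaluate, random_candidate, repair, ga) {
  pop_n <- ga$population_size
  mu <- ga$mutation_rate %||% (1 / L)
  pop <- t(vapply(seq_len(pop_n), function(i) repair(random_candidate()),
                  integer(L)))
  fitness <- evaluate(pop)
  best_i <- which.max(fitness)
  best <- list(bits = pop[best_i, ], fitness = fitness[best_i])
  trace <- vector("list", ga$generations)
  n_eval <- pop_n
  for (g in seq_len(ga$generations)) {
    ord <- order(fitness, decreasing = TRUE)
    elite_idx <- head(ord, ga$elitism)
    n_off <- pop_n - length(elite_idx)
    n_imm <- min(n_off, floor(ga$immigrant_fraction * pop_n))
    offspring <- matrix(0L, n_off, L)
    for (j in seq_len(n_off)) {
      if (j > n_off - n_imm) {               # doped random immigrant
        child <- random_candidate()
      } else {
        p1 <- tournament_pick(fitness, ga$tournament_p)
        if (runif(1) < ga$crossover_rate) {
          p2 <- tournament_pick(fitness, ga$tournament_p)
          take <- runif(L) < 0.5
          child <- ifelse(take, pop[p1, ], pop[p2, ])
        } else {
          child <- pop[p1, ]
        }
        flip <- runif(L) < mu
        child[flip] <- 1L - child[flip]
      }
      offspring[j, ] <- repair(as.integer(child))
    }
    off_fit <- evaluate(offspring)
    n_eval <- n_eval + n_off
    pop <- rbind(pop[elite_idx, , drop = FALSE], offspring)
    fitness <- c(fitness[elite_idx], off_fit)
    gen_best <- which.max(fitness)
    if (fitness[gen_best] > best$fitness) {
      best <- list(bits = pop[gen_best, ], fitness = fitness[gen_best])
    }
    trace[[g]] <- tibble(generation = g, best_fitness = best$fitness,
                         mean_fitness = mean(fitness))
  }
  list(best = best, trace = bind_rows(trace), n_evaluations = n_eval)
}

tournament_pick <- function(fitness, p_win) {
  ij <- sample.int(length(fitness), 2, replace = TRUE)
  hi <- if (fitness[ij[1]] >= fitness[ij[2]]) ij[1] else ij[2]
  lo <- ij[1] + ij[2] - hi
  if (runif(1) < p_win) hi else lo
}

#' Optimise a representative train/test split (the T&T stage)
#'
#' Evolves a training-set membership vector so that each half is
#' statistically representative of the full sample: the fitness of a split
#' is the worse of the two cross-prediction accuracies (train on A, test on
#' B; train on B, test on A), each averaged over the enabled learners. A
#' split on which models generalise equally well in both directions cannot
#' have concentrated uncharacteristic records in either half.
#'
#' @param indicators Indicator tibble from [expand_indicators()]; outcome
#'   columns are never used as features.
#' @param outcome Binary outcome vector; defaults to the cohort outcome
#'   stored on `indicators`.
#' @param ga A [ga_config()].
#' @param bank A [learner_bank()].
#' @param target_fraction Training-set fraction (default 0.5).
#' @return An object of class `"twist_split"`: `membership` (1 = training),
#'   `fitness`, `trace` (per-generation best/mean fitness) and split
#'   composition statistics.
#' @export
optimize_split <- function(indicators, outcome = NULL, ga = ga_config(),
                           bank = learner_bank(), target_fraction = 0.5) {
  X <- feature_matrix(indicators)
  y <- outcome %||% attr(indicators, "outcome")
  check_two_classes(y)
  n <- nrow(X)
  n_train <- round(target_fraction * n)
  if (n_train < 2 || n - n_train < 2) {
    abort("Both split halves need at least 2 records.",
          class = "twistmap_error_twist")
  }
  repair <- function(bits) repair_split(bits, y, n_train)
  random_candidate <- function() {
    bits <- integer(n); bits[sample.int(n, n_train)] <- 1L; bits
  }
  evaluate <- function(pop) {
    vapply(seq_len(nrow(pop)), function(i) {
      m <- pop[i, ] == 1L
      min(bank_accuracy(bank, X[m, , drop = FALSE], y[m],
                        X[!m, , drop = FALSE], y[!m]),
          bank_accuracy(bank, X[!m, , drop = FALSE], y[!m],
                        X[m, , drop = FALSE], y[m]))
    }, numeric(1))
  }
  res <- with_preserved_seed(ga$seed,
                             run_ga(n, evaluate, random_candidate, repair, ga))
  membership <- res$best$bits
  structure(list(membership = membership, fitness = res$best$fitness,
                 trace = res$trace, target_fraction = target_fraction,
                 n_train = sum(membership), n_test = n - sum(membership),
                 case_fraction_train = mean(y[membership == 1L]),
                 case_fraction_test = mean(y[membership == 0L]),
                 n_evaluations = res$n_evaluations, ga = ga),
            class = "twist_split")
}

# Force the training count to n_train and at least one case and one
# control on each side.
repair_split <- function(bits, y, n_train) {
  bits <- as.integer(bits)
  excess <- sum(bits) - n_train
  if (excess > 0) {
    bits[sample(which(bits == 1L), excess)] <- 0L
  } else if (excess < 0) {
    bits[sample(which(bits == 0L), -excess)] <- 1L
  }
  for (cls in c(0L, 1L)) {
    in_cls <- y == cls
    if (sum(bits[in_cls]) == 0L) {
      give <- sample(which(in_cls & bits == 0L), 1)
      take <- sample(which(!in_cls & bits == 1L), 1)
      bits[give] <- 1L; bits[take] <- 0L
    }
    if (sum(bits[in_cls]) == sum(in_cls)) {
      give <- sample(which(in_cls & bits == 1L), 1)
      take <- sample(which(!in_cls & bits == 0L), 1)
      bits[give] <- 0L; bits[take] <- 1L
    }
  }
  bits
}

#' Evolve a minimal predictive indicator mask (the IS stage)
#'
#' Evolves a 0/1 vector over the indicator columns (1 = indicator retained)
#' to maximise held-out classification of cases against controls: candidate
#' masks are trained on the split's training half and scored on its testing
#' half, with fitness `1 - cost` averaged over the enabled learners. Fitter
#' masks are overrepresented in the next generation, while tournament
#' retention of weaker parents and random immigrants keep sub-optimal
#' material in play. Outcome columns are excluded from the search space.
#'
#' @inheritParams optimize_split
#' @param split A `"twist_split"` (or any 0/1 membership vector, 1 =
#'   training); frozen during the search, so no learner ever sees
#'   testing-set labels while fitting.
#' @param cost Cost passed to [confusion_cost()].
#' @return An object of class `"twist_mask"`: named `bits` over feature
#'   columns, best-ever `fitness`, the per-generation `trace`
#'   (non-decreasing best fitness), and bookkeeping fields.
#' @export
select_features <- function(indicators, outcome = NULL, split,
                            ga = ga_config(), bank = learner_bank(),
                            cost = "misclassification") {
  X <- feature_matrix(indicators)
  y <- outcome %||% attr(indicators, "outcome")
  check_two_classes(y)
  membership <- if (inherits(split, "twist_split")) split$membership else split
  stopifnot(length(membership) == nrow(X))
  tr <- membership == 1L
  check_two_classes(y[tr]); check_two_classes(y[!tr])
  Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
  Xte <- X[!tr, , drop = FALSE]; yte <- y[!tr]
  L <- ncol(X)
  repair <- function(bits) {
    if (sum(bits) == 0L) bits[sample.int(L, 1)] <- 1L
    bits
  }
  evaluate <- function(pop) {
    vapply(seq_len(nrow(pop)), function(i) {
      m <- pop[i, ] == 1L
      bank_accuracy(bank, Xtr[, m, drop = FALSE], ytr,
                    Xte[, m, drop = FALSE], yte, cost = cost)
    }, numeric(1))
  }
  random_candidate <- function() as.integer(runif(L) < 0.5)
  res <- with_preserved_seed(ga$seed,
                             run_ga(L, evaluate, random_candidate, repair, ga))
  bits <- setNames(res$best$bits, colnames(X))
  structure(list(bits = bits, fitness = res$best$fitness,
                 trace = res$trace, n_selected = sum(bits),
                 n_columns = L, n_evaluations = res$n_evaluations,
                 info = indicator_info(indicators), ga = ga, bank = bank),
            class = "twist_mask")
}

check_two_classes <- function(y) {
  if (length(unique(y)) < 2) {
    abort("Outcome must contain both classes.",
          class = "twistmap_error_twist")
  }
  invisible(y)
}

#' Apply a mask, keeping the selected indicator columns
#'
#' @param indicators Indicator tibble.
#' @param mask A `"twist_mask"`, or a named/plain 0/1 vector over the
#'   feature columns. Outcome columns (`Event`/`No_Event`) are always kept.
#' @return The filtered indicator tibble (metadata updated).
#' @export
apply_mask <- function(indicators, mask) {
  info <- indicator_info(indicators)
  bits <- if (inherits(mask, "twist_mask")) mask$bits else mask
  feat <- info$column[info$role == "feature"]
  stopifnot(length(bits) == length(feat))
  keep <- c(feat[bits == 1L], info$column[info$role == "outcome"])
  out <- indicators[, keep, drop = FALSE]
  attr(out, "indicator_info") <- info[match(keep, info$column), ]
  attr(out, "outcome") <- attr(indicators, "outcome")
  out
}

#' @export
print.twist_mask <- function(x, ...) {
  cat(sprintf(
    "TWIST indicator mask: %d of %d columns retained (held-out fitness %.3f)\n",
    x$n_selected, x$n_columns, x$fitness))
  invisible(x)
}

#' @export
print.twist_split <- function(x, ...) {
  cat(sprintf(
    "TWIST split: %d train / %d test (case fraction %.2f / %.2f), fitness %.3f\n",
    x$n_train, x$n_test, x$case_fraction_train, x$case_fraction_test,
    x$fitness))
  invisible(x)
}
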