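# Small, fast GA settings for structural tests; the full-scale search is
# exercised in test-acceptance.R.
fast_ga <- function(...) ga_config(population_size = 20, generations = 15, ...)
nb_bank <- learner_bank("naive_bayes")

small_cohort_indicators <- function(seed = 1, effect = 0.8) {
  cfg <- sim_config(n_cases = 60, n_controls = 60, n_snps = 4,
                    n_continuous = 0, n_binary = 1,
                    allele_freqs = rep(0.4, 4),
                    liability_weights = if (effect == 0) NULL else
                      tibble::tibble(variable = c("snp01", "smoking"),
                                     category = c(3L, 2L),
                                     weight = c(effect, effect)),
                    prevalence = 0.4, pool_size = 1500, seed = seed)
  expand_indicators(generate_cohort(cfg)$cohort)
}

test_that("best-ever fitness trace is monotonically non-decreasing", {
  ind <- small_cohort_indicators()
  split <- optimize_split(ind, ga = fast_ga(seed = 2), bank = nb_bank)
  mask <- select_features(ind, split = split, ga = fast_ga(seed = 3),
                          bank = nb_bank)
  expect_true(all(diff(split$trace$best_fitness) >= 0))
  expect_true(all(diff(mask$trace$best_fitness) >= 0))
  expect_equal(mask$fitness, max(mask$trace$best_fitness))
  expect_gte(mask$n_selected, 1)
})

test_that("the GA is a no-op for a frozen singleton population", {
  ind <- small_cohort_indicators()
  split <- optimize_split(ind, ga = fast_ga(seed = 2), bank = nb_bank)
  ga0 <- ga_config(population_size = 1, generations = 10,
                   crossover_rate = 0, mutation_rate = 0,
                   immigrant_fraction = 0, elitism = 0, seed = 4)
  mask <- select_features(ind, split = split, ga = ga0, bank = nb_bank)
  expect_equal(length(unique(mask$trace$best_fitness)), 1)
  expect_equal(mask$trace$mean_fitness, mask$trace$best_fitness)
})

test_that("optimized splits are representative of the case fraction", {
  ind <- small_cohort_indicators(seed = 5)
  y <- attr(ind, "outcome")
  split <- optimize_split(ind, ga = fast_ga(seed = 6), bank = nb_bank)
  full <- mean(y)
  expect_lt(abs(split$case_fraction_train - full), 0.1)
  expect_lt(abs(split$case_fraction_test - full), 0.1)
  expect_equal(split$n_train + split$n_test, length(y))
  expect_gte(min(split$n_train, split$n_test), 2)
})

test_that("a duplicated dataset admits a maximal-fitness mirror split", {
  # each record twice: assigning one copy to each side makes both halves
  # identical, so cross-prediction is as good as training accuracy
  ind <- small_cohort_indicators(seed = 7)
  X2 <- dplyr::bind_rows(ind, ind)
  attr(X2, "indicator_info") <- indicator_info(ind)
  y <- attr(ind, "outcome")
  attr(X2, "outcome") <- c(y, y)
  n <- nrow(ind)
  F2 <- feature_matrix(X2)
  y2 <- c(y, y)
  split_fitness <- function(m) {
    min(twistmap:::bank_accuracy(nb_bank, F2[m == 1L, ], y2[m == 1L],
                                 F2[m == 0L, ], y2[m == 0L]),
        twistmap:::bank_accuracy(nb_bank, F2[m == 0L, ], y2[m == 0L],
                                 F2[m == 1L, ], y2[m == 1L]))
  }
  fit_mirror <- split_fitness(c(rep(1L, n), rep(0L, n)))
  random_fits <- withr::with_seed(80, vapply(1:30, function(i) {
    m <- integer(2 * n); m[sample.int(2 * n, n)] <- 1L
    split_fitness(m)
  }, numeric(1)))
  # identical halves generalise at least as well as typical random splits
  expect_gte(fit_mirror, median(random_fits))
  # and the optimiser finds a split at least that representative
  split <- optimize_split(X2, ga = fast_ga(seed = 8), bank = nb_bank)
  expect_gte(split$fitness, fit_mirror - 0.02)
})

test_that("search is deterministic under a fixed seed", {
  ind <- small_cohort_indicators(seed = 9)
  s1 <- optimize_split(ind, ga = fast_ga(seed = 10), bank = nb_bank)
  s2 <- optimize_split(ind, ga = fast_ga(seed = 10), bank = nb_bank)
  expect_identical(s1$membership, s2$membership)
  m1 <- select_features(ind, split = s1, ga = fast_ga(seed = 11),
                        bank = nb_bank)
  m2 <- select_features(ind, split = s2, ga = fast_ga(seed = 11),
                        bank = nb_bank)
  expect_identical(m1$bits, m2$bits)
  expect_identical(m1$trace, m2$trace)
})

test_that("outcome columns are never part of the search space", {
  ind <- small_cohort_indicators(seed = 12)
  split <- optimize_split(ind, ga = fast_ga(seed = 13), bank = nb_bank)
  mask <- select_features(ind, split = split, ga = fast_ga(seed = 14),
                          bank = nb_bank)
  expect_false(any(c("Event", "No_Event") %in% names(mask$bits)))
  expect_equal(mask$n_columns,
               sum(indicator_info(ind)$role == "feature"))
})

test_that("apply_mask keeps selected features plus outcome columns", {
  ind <- small_cohort_indicators(seed = 15)
  bits <- setNames(rep(0L, 14), indicator_info(ind)$column[1:14])
  bits[c(1, 5, 9)] <- 1L
  out <- apply_mask(ind, bits)
  expect_setequal(names(out), c(names(bits)[bits == 1L], "Event", "No_Event"))
  expect_equal(nrow(indicator_info(out)), 5)
})

test_that("planted informative indicators dominate selection (smoke)", {
  cfg <- recovery_sim_config(seed = 42)
  gen <- generate_cohort(cfg)
  ind <- expand_indicators(gen$cohort)
  split <- optimize_split(ind, ga = ga_config(population_size = 20,
                                              generations = 10, seed = 43),
                          bank = nb_bank)
  mask <- select_features(ind, split = split,
                          ga = ga_config(population_size = 60,
                                         generations = 80, seed = 44),
                          bank = nb_bank)
  sel <- names(mask$bits)[mask$bits == 1L]
  # short search: most, not necessarily all, planted columns surface
  expect_gte(sum(gen$truth$informative_indicators %in% sel), 2)
  expect_gt(mask$fitness, 0.6)
})

test_that("complementary binary indicators are mostly deduplicated", {
  # both smoking_yes and smoking_no carry the same information; selection
  # usually retains only one of the pair
  both <- 0
  for (s in 1:5) {
    ind <- small_cohort_indicators(seed = 20 + s)
    split <- optimize_split(ind, ga = fast_ga(seed = 30 + s), bank = nb_bank)
    mask <- select_features(ind, split = split,
                            ga = ga_config(population_size = 40,
                                           generations = 60, seed = 40 + s),
                            bank = nb_bank)
    sel <- names(mask$bits)[mask$bits == 1L]
    if (all(c("smoking_yes", "smoking_no") %in% sel)) both <- both + 1
  }
  expect_lte(both, 2)
})
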