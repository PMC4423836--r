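#' Configure a synthetic case-control cohort
#'
#' Defines the generative model for a synthetic cohort: SNP genotypes drawn
#' from Hardy-Weinberg proportions, continuous phenotypes built from additive
#' per-allele genetic effects plus correlated Gaussian noise, binary traits,
#' and a binary outcome from a liability-threshold model. Liability weights
#' are placed on indicator categories (a tertile of a phenotype, a genotype
#' class, the yes level of a binary trait), so the set of informative
#' indicator columns is known exactly and is returned as planted truth by
#' [generate_cohort()].
#'
#' @param n_cases,n_controls Case and control counts of the sampled cohort.
#' @param n_snps Number of SNP loci (`genotype3` variables, one SNP per
#'   locus, no linkage disequilibrium between loci).
#' @param n_continuous Number of continuous phenotypes.
#' @param n_binary Number of binary traits (the first is named `smoking`).
#' @param allele_freqs Minor allele frequencies, length `n_snps`.
#' @param effect_matrix `n_snps` by `n_continuous` additive effects, in
#'   phenotype standard-deviation units per minor allele.
#' @param phenotype_correlation Positive-definite correlation matrix of the
#'   phenotype noise.
#' @param binary_prevalence Probability of the yes level for each binary
#'   trait.
#' @param liability_weights Tibble with columns `variable`, `category`
#'   (1-based category index) and `weight`: each row adds
#'   `weight * indicator` to the disease liability. May have zero rows
#'   (pure-noise outcome).
#' @param prevalence Target case fraction in the source population; the
#'   liability threshold is set to hit it.
#' @param hub_variable Optional name of a variable designated as a hub
#'   (given effects on several phenotypes in [nphs2_like_config()]).
#' @param pool_size Size of the population pool cases/controls are sampled
#'   from; default `max(4000, 20 * (n_cases + n_controls))`.
#' @param seed Integer seed; all stochastic draws flow from it.
#'
#' @return A list of class `"sim_config"`.
#' @seealso [nphs2_like_config()] for the default study-like configuration.
#' @export
sim_config <- function(n_cases = 102, n_controls = 150,
                       n_snps = 37, n_continuous = 14, n_binary = 1,
                       allele_freqs = NULL,
                       effect_matrix = NULL,
                       phenotype_correlation = NULL,
                       binary_prevalence = 0.28,
                       liability_weights = NULL,
                       prevalence = 0.15,
                       hub_variable = NULL,
                       pool_size = NULL,
                       seed = 1L) {
  if (is.null(allele_freqs)) {
    allele_freqs <- if (n_snps == 0) numeric(0) else
      seq(0.15, 0.5, length.out = n_snps)
  }
  stopifnot(length(allele_freqs) == n_snps,
            all(allele_freqs > 0), all(allele_freqs < 1))
  if (is.null(effect_matrix)) {
    effect_matrix <- matrix(0, n_snps, n_continuous)
  }
  stopifnot(nrow(effect_matrix) == n_snps,
            ncol(effect_matrix) == n_continuous)
  if (is.null(phenotype_correlation)) {
    phenotype_correlation <- block_correlation(n_continuous, rho = 0.35)
  }
  stopifnot(isSymmetric(unname(phenotype_correlation)),
            nrow(phenotype_correlation) == n_continuous)
  # fails here if not positive definite
  if (n_continuous > 0) chol(phenotype_correlation)
  if (is.null(liability_weights)) {
    liability_weights <- tibble(variable = character(),
                                category = integer(), weight = numeric())
  }
  binary_prevalence <- rep_len(binary_prevalence, n_binary)
  if (is.null(pool_size)) {
    pool_size <- max(4000L, 20L * (n_cases + n_controls))
  }
  cfg <- list(n_cases = n_cases, n_controls = n_controls, n_snps = n_snps,
              n_continuous = n_continuous, n_binary = n_binary,
              allele_freqs = allele_freqs, effect_matrix = effect_matrix,
              phenotype_correlation = phenotype_correlation,
              binary_prevalence = binary_prevalence,
              liability_weights = liability_weights,
              prevalence = prevalence, hub_variable = hub_variable,
              pool_size = pool_size, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Block-exchangeable correlation matrix
#'
#' Helper for phenotype noise structure: variables are grouped into
#' contiguous blocks (biomarkers that cluster, e.g. lipid traits) with
#' within-block correlation `rho` and independence between blocks.
#'
#' @param p Number of variables.
#' @param rho Within-block correlation in `[0, 1)`.
#' @param n_blocks Number of blocks (default 3, sizes as equal as possible).
#' @return A `p` by `p` correlation matrix.
#' @export
block_correlation <- function(p, rho = 0.35, n_blocks = 3) {
  if (p == 0) return(matrix(numeric(0), 0, 0))
  blocks <- sort(rep_len(seq_len(min(n_blocks, p)), p))
  m <- outer(blocks, blocks, "==") * rho
  diag(m) <- 1
  m
}

#' Study-like default configuration
#'
#' Returns the default synthetic cohort configuration mirroring the design
#' of the motivating prospective CHD study: 102 cases and 150 randomly drawn
#' controls, 37 SNP loci, 14 continuous phenotypes plus one binary trait
#' (smoking), and one designated hub SNP with additive effects on six
#' phenotypes. Several indicator categories (smoking yes, upper or lower
#' tertiles of a few biomarkers, two genotype classes) carry liability
#' weight, giving a planted set of informative indicators.
#'
#' @param seed Integer seed (default 1).
#' @return A `"sim_config"` object.
#' @export
nphs2_like_config <- function(seed = 1L) {
  n_snps <- 37; n_continuous <- 14
  effects <- matrix(0, n_snps, n_continuous)
  effects[1, 1:6] <- 0.35           # hub SNP influences six phenotypes
  effects[2, 1] <- 0.3              # two further SNP-phenotype links
  effects[3, 7] <- 0.25
  lw <- tibble(
    variable = c("smoking", "pheno01", "pheno02", "pheno03", "pheno04",
                 "snp02", "snp03", "snp04"),
    category = c(2L, 3L, 3L, 1L, 3L, 3L, 2L, 3L),
    weight   = c(0.5, 0.45, 0.4, 0.35, 0.3, 0.4, 0.3, 0.3)
  )
  sim_config(n_cases = 102, n_controls = 150, n_snps = n_snps,
             n_continuous = n_continuous, n_binary = 1,
             effect_matrix = effects, liability_weights = lw,
             hub_variable = "snp01", seed = seed)
}

#' Compact recovery-benchmark configuration
#'
#' A small planted-truth design used to probe whether the TWIST selection
#' stage recovers known informative indicators: 300 cases and 300 controls,
#' 10 SNP loci and two binary traits (34 indicator columns in all), with
#' four indicators from four different variables carrying liability weight
#' `effect` each. With `effect = 0` the outcome is pure noise.
#'
#' @param seed Integer seed.
#' @param effect Liability weight shared by the four informative indicators
#'   (default 0.8; `0` gives a null cohort).
#' @return A `"sim_config"`.
#' @export
recovery_sim_config <- function(seed = 1L, effect = 0.8) {
  lw <- tibble(
    variable = c("snp01", "snp03", "smoking", "bin02"),
    category = c(3L, 1L, 2L, 2L),
    weight   = rep(effect, 4)
  )
  if (effect == 0) lw <- lw[0, ]
  sim_config(n_cases = 300, n_controls = 300, n_snps = 10,
             n_continuous = 0, n_binary = 2,
             allele_freqs = seq(0.35, 0.5, length.out = 10),
             liability_weights = lw, prevalence = 0.4,
             pool_size = 4000, seed = seed)
}

sim_schema <- function(config) {
  nm <- c(sprintf("pheno%02d", seq_len(config$n_continuous)),
          binary_names(config$n_binary),
          sprintf("snp%02d", seq_len(config$n_snps)))
  kd <- c(rep("continuous", config$n_continuous),
          rep("binary", config$n_binary),
          rep("genotype3", config$n_snps))
  cohort_schema(nm, kd)
}

binary_names <- function(n_binary) {
  if (n_binary == 0) return(character(0))
  if (n_binary == 1) return("smoking")
  c("smoking", sprintf("bin%02d", 2:n_binary))
}

#' Simulate a raw population sample (no case-control sampling)
#'
#' Draws `n` individuals from the generative model of a [sim_config()]:
#' genotypes from Hardy-Weinberg proportions p^2 / 2pq / q^2, phenotypes as
#' additive genetic effects plus correlated Gaussian noise, binary traits,
#' the latent liability and the binary outcome (liability above the
#' threshold hitting the target prevalence).
#'
#' @param config A `"sim_config"`.
#' @param n Number of individuals.
#' @param seed Seed (default `config$seed`).
#' @return A cohort tibble (schema attached) with `outcome` and a
#'   `liability` column.
#' @export
simulate_population <- function(config, n, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  schema <- sim_schema(config)
  with_preserved_seed(seed, {
    geno <- vapply(config$allele_freqs,
                   function(p) rbinom(n, 2L, p), integer(n))
    if (config$n_snps == 0) geno <- matrix(integer(0), n, 0)
    pheno <- if (config$n_continuous > 0) {
      matrix(rnorm(n * config$n_continuous), n) %*%
        chol(config$phenotype_correlation)
    } else {
      matrix(numeric(0), n, 0)
    }
    if (config$n_snps > 0 && config$n_continuous > 0) {
      pheno <- pheno + geno %*% config$effect_matrix
    }
    bin <- vapply(config$binary_prevalence,
                  function(pr) rbinom(n, 1L, pr), integer(n))
    if (config$n_binary == 0) bin <- matrix(integer(0), n, 0)
    cohort <- as_tibble(as.data.frame(cbind(pheno, bin, geno)))
    names(cohort) <- schema$name
    liab <- liability_score(cohort, schema, config$liability_weights) +
      rnorm(n)
    thr <- stats::quantile(liab, 1 - config$prevalence, names = FALSE)
    cohort$liability <- liab
    cohort$outcome <- as.integer(liab > thr)
    attr(cohort, "schema") <- schema
    cohort
  })
}

# Sum of category-indicator liability contributions (no noise term).
liability_score <- function(cohort, schema, weights) {
  liab <- numeric(nrow(cohort))
  if (nrow(weights) == 0) return(liab)
  for (i in seq_len(nrow(weights))) {
    v <- weights$variable[i]
    k <- weights$category[i]
    j <- match(v, schema$name)
    if (is.na(j)) {
      abort(paste0("Liability weight on unknown variable: ", v),
            class = "twistmap_error_sim")
    }
    cat <- switch(schema$kind[j],
      continuous = tertile_bin(cohort[[v]]),
      genotype3  = as.integer(cohort[[v]]) + 1L,
      binary     = as.integer(cohort[[v]]) + 1L
    )
    liab <- liab + weights$weight[i] * (cat == k)
  }
  liab
}

#' Generate a synthetic case-control cohort with planted truth
#'
#' Simulates a population pool from the configured model, then samples
#' exactly `n_cases` cases and `n_controls` controls from it (the emulated
#' design of down-sampled controls), returning the cohort together with the
#' planted ground truth: the indicator columns carrying nonzero liability
#' weight and the designated hub variable.
#'
#' @param config A `"sim_config"`.
#' @param seed Seed (default `config$seed`).
#' @return A list with elements `cohort` (tibble with schema attribute and
#'   `outcome` column) and `truth` (list with `informative_indicators`,
#'   `hub_variable`, `liability_weights`).
#' @export
generate_cohort <- function(config, seed = config$seed) {
  pool <- simulate_population(config, config$pool_size, seed = seed)
  cases <- which(pool$outcome == 1)
  controls <- which(pool$outcome == 0)
  if (length(cases) < config$n_cases || length(controls) < config$n_controls) {
    abort(sprintf(
      "Infeasible case-control design: pool of %d yields %d cases / %d controls.",
      config$pool_size, length(cases), length(controls)),
      class = "twistmap_error_sim")
  }
  schema <- attr(pool, "schema")
  with_preserved_seed(seed + 101L, {
    take <- c(sample(cases, config$n_cases),
              sample(controls, config$n_controls))
    take <- sample(take)    # shuffle case/control order
    cohort <- pool[take, setdiff(names(pool), "liability"), drop = FALSE]
    attr(cohort, "schema") <- schema
    truth <- list(
      informative_indicators = informative_labels(config, schema),
      hub_variable = config$hub_variable,
      liability_weights = config$liability_weights
    )
    list(cohort = cohort, truth = truth)
  })
}

informative_labels <- function(config, schema) {
  w <- config$liability_weights
  w <- w[w$weight != 0, , drop = FALSE]
  if (nrow(w) == 0) return(character(0))
  vapply(seq_len(nrow(w)), function(i) {
    j <- match(w$variable[i], schema$name)
    paste(w$variable[i], schema$labels[[j]][w$category[i]], sep = "_")
  }, character(1))
}

#' Generate paired groups with different planted correlation density
#'
#' Builds a cohort whose control rows carry denser inter-variable
#' correlations than its case rows: continuous variables fall into blocks
#' with within-block correlation `rho_cases` among cases and `rho_controls`
#' among controls. Used to probe the directional behaviour of the per-group
#' graph complexity contrast (a more correlated group yields a denser
#' maximally regular graph and a larger topological entropy).
#'
#' @param n_cases,n_controls Group sizes.
#' @param n_vars Number of continuous variables.
#' @param rho_cases,rho_controls Within-block correlations per group.
#' @param n_blocks Number of variable blocks (default 3).
#' @param seed Integer seed.
#' @return Cohort tibble (schema attribute, `outcome` = 1 for cases).
#' @export
generate_contrast_cohort <- function(n_cases = 120, n_controls = 120,
                                     n_vars = 12, rho_cases = 0.15,
                                     rho_controls = 0.55, n_blocks = 3,
                                     seed = 1L) {
  schema <- cohort_schema(sprintf("var%02d", seq_len(n_vars)), "continuous")
  draw <- function(n, rho) {
    matrix(rnorm(n * n_vars), n) %*%
      chol(block_correlation(n_vars, rho, n_blocks))
  }
  with_preserved_seed(seed, {
    x <- rbind(draw(n_cases, rho_cases), draw(n_controls, rho_controls))
    cohort <- as_tibble(as.data.frame(x))
    names(cohort) <- schema$name
    cohort$outcome <- rep(c(1L, 0L), c(n_cases, n_controls))
    attr(cohort, "schema") <- schema
    cohort
  })
}

#' Write planted truth as JSON
#'
#' @param truth The `truth` element of [generate_cohort()]'s result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(informative_indicators = truth$informative_indicators,
         hub_variable = truth$hub_variable,
         liability_weights = truth$liability_weights),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
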