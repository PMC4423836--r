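#' Configure an end-to-end pipeline run
#'
#' Bundles every stage's settings: the cohort source (a simulated design or
#' a cohort tibble with its schema), the evolutionary search, the learner
#' bank, the Auto-CM, and the graph stage. All stage seeds are derived from
#' the single pipeline seed.
#'
#' @param sim Optional [sim_config()]; the cohort is simulated when given.
#' @param cohort Optional cohort tibble (used when `sim` is `NULL`).
#' @param schema Schema for `cohort`; defaults to its attribute.
#' @param ga A [ga_config()] for both TWIST stages.
#' @param bank A [learner_bank()].
#' @param split_fraction Training fraction of the T&T stage (default 0.5).
#' @param skip_selection If `TRUE`, skip TWIST and map all indicators
#'   (mask of all ones).
#' @param autocm Named list of [train_autocm()] parameters.
#' @param meta_k,meta_drop,meta_support Meta-MST resampling settings.
#' @param mrg_floor Similarity floor for MRG link re-introduction.
#' @param seed Integer pipeline seed (required; drives every stage).
#' @param out_dir Optional output directory; when set, [run_pipeline()]
#'   writes edge lists, the mask, traces and a run manifest there.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = NULL, cohort = NULL, schema = NULL,
                            ga = ga_config(), bank = learner_bank(),
                            split_fraction = 0.5, skip_selection = FALSE,
                            autocm = list(), meta_k = 10, meta_drop = 0.1,
                            meta_support = 9, mrg_floor = 0.33,
                            seed = 1L, out_dir = NULL) {
  if (is.null(sim) && is.null(cohort)) {
    abort("Provide either a sim config or a cohort.",
          class = "twistmap_error_pipeline")
  }
  structure(list(sim = sim, cohort = cohort, schema = schema, ga = ga,
                 bank = bank, split_fraction = split_fraction,
                 skip_selection = skip_selection, autocm = autocm,
                 meta_k = meta_k, meta_drop = meta_drop,
                 meta_support = meta_support, mrg_floor = mrg_floor,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full pipeline: recode, TWIST, Auto-CM, graphs
#'
#' Executes the stages end to end: indicator recoding of the cohort (with
#' `Event`/`No_Event` appended), optimisation of a representative
#' train/test split, evolutionary indicator selection, Auto-CM training on
#' the selected indicators plus the outcome nodes, the MST, the Meta-MST
#' stability filter, and the per-group (case vs control) MRG complexity
#' contrast. Identical configurations and seeds reproduce identical
#' results; when `out_dir` is set, artifacts and a manifest are written
#' there.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `"twist_pipeline"` with elements `cohort`,
#'   `truth` (when simulated), `indicators`, `split`, `mask`, `selected`,
#'   `model`, `similarity`, `mst`, `meta`, `contrast`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "twistmap_error_pipeline", parent = e)
    })
  }
  truth <- NULL
  cohort <- stage("cohort", {
    if (!is.null(config$sim)) {
      gen <- generate_cohort(config$sim, seed = seed)
      truth <- gen$truth
      gen$cohort
    } else {
      sc <- config$schema %||% attr(config$cohort, "schema")
      validate_cohort(config$cohort, sc)
    }
  })
  indicators <- stage("recode", expand_indicators(cohort))
  inform(sprintf("recode: %d records x %d indicator columns (+2 outcome)",
                 nrow(indicators),
                 sum(indicator_info(indicators)$role == "feature")))
  split <- NULL
  mask <- NULL
  if (config$skip_selection) {
    selected <- indicators
  } else {
    split <- stage("split", optimize_split(
      indicators, ga = replace_seed(config$ga, seed + 1L),
      bank = config$bank, target_fraction = config$split_fraction))
    mask <- stage("select", select_features(
      indicators, split = split,
      ga = replace_seed(config$ga, seed + 2L), bank = config$bank))
    selected <- apply_mask(indicators, mask)
    inform(sprintf("select: %d of %d indicator columns retained",
                   mask$n_selected, mask$n_columns))
  }
  model <- stage("autocm", do.call(train_autocm,
                                   c(list(X = selected), config$autocm)))
  S <- similarity_matrix(model)
  mst <- stage("mst", minimum_spanning_tree(to_distances(S)))
  meta <- stage("meta_mst", do.call(meta_mst, c(
    list(indicators = selected, k = config$meta_k,
         drop_fraction = config$meta_drop,
         support_threshold = config$meta_support, seed = seed + 3L,
         strata = attr(indicators, "outcome")),
    config$autocm)))
  contrast <- stage("contrast", do.call(group_complexity_contrast, c(
    list(indicators = selected, floor = config$mrg_floor),
    config$autocm)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("twistmap")),
    seed = seed,
    simulated = !is.null(config$sim),
    n_records = nrow(cohort),
    n_indicators = sum(indicator_info(indicators)$role == "feature"),
    n_selected = if (is.null(mask)) NA else mask$n_selected,
    skip_selection = config$skip_selection,
    ga = unclass(config$ga), bank = config$bank$enabled,
    autocm = config$autocm,
    meta = list(k = config$meta_k, drop = config$meta_drop,
                support = config$meta_support),
    mrg_floor = config$mrg_floor)
  bundle <- structure(
    list(cohort = cohort, truth = truth, indicators = indicators,
         split = split, mask = mask, selected = selected, model = model,
         similarity = S, mst = mst, meta = meta, contrast = contrast,
         manifest = manifest),
    class = "twist_pipeline")
  if (!is.null(config$out_dir)) write_pipeline(bundle, config$out_dir)
  bundle
}

replace_seed <- function(ga, seed) {
  ga$seed <- as.integer(seed)
  ga
}

write_pipeline <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_edge_list(bundle$mst, file.path(dir, "mst_edges.csv"))
  write_edge_list(bundle$meta, file.path(dir, "meta_mst_edges.csv"))
  write_edge_list(bundle$contrast$case$mrg$graph,
                  file.path(dir, "mrg_cases_edges.csv"))
  write_edge_list(bundle$contrast$control$mrg$graph,
                  file.path(dir, "mrg_controls_edges.csv"))
  if (!is.null(bundle$mask)) {
    m <- bundle$mask
    jsonlite::write_json(
      list(selected = names(m$bits)[m$bits == 1L],
           removed = names(m$bits)[m$bits == 0L],
           fitness = m$fitness),
      file.path(dir, "mask.json"), auto_unbox = TRUE, digits = NA)
    readr::write_csv(m$trace, file.path(dir, "selection_trace.csv"),
                     progress = FALSE)
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(dir)
}

#' Summarise a pipeline run
#'
#' Produces the human-readable account of a completed run: selected and
#' removed indicator counts per parent variable, the hub list, the edges on
#' the `Event` to `No_Event` path of the MST, the nodes reachable from
#' `Event` without passing `No_Event` (a direct path of association with
#' the event), and the per-group complexity contrast.
#'
#' @param bundle A `"twist_pipeline"` from [run_pipeline()].
#' @return A list of class `"twist_pipeline_report"`.
#' @export
pipeline_report <- function(bundle) {
  if (!inherits(bundle, "twist_pipeline") || is.null(bundle$mst)) {
    abort("pipeline_report() needs a completed pipeline bundle.",
          class = "twistmap_error_pipeline")
  }
  info <- indicator_info(bundle$indicators)
  feat <- info[info$role == "feature", ]
  if (!is.null(bundle$mask)) {
    feat$selected <- as.integer(bundle$mask$bits[feat$column])
  } else {
    feat$selected <- 1L
  }
  per_parent <- feat %>%
    group_by(.data$parent) %>%
    summarise(n_indicators = dplyr::n(),
              n_selected = sum(.data$selected), .groups = "drop")
  hubs <- hub_nodes(bundle$mst, top_k = 5)
  has_events <- all(c("Event", "No_Event") %in% bundle$mst$nodes)
  event_path <- if (has_events) {
    tree_path(bundle$mst, "Event", "No_Event")
  } else character(0)
  event_side <- if (has_events) {
    setdiff(reachable_without(bundle$mst, "Event", "No_Event"), "Event")
  } else character(0)
  structure(list(
    n_records = nrow(bundle$cohort),
    n_indicators = nrow(feat),
    n_selected = sum(feat$selected),
    per_parent = per_parent,
    hubs = hubs,
    event_path = event_path,
    event_side_nodes = event_side,
    meta_n_edges = nrow(bundle$meta$edges),
    delta_H = bundle$contrast$delta$H,
    delta_E_G = bundle$contrast$delta$E_G,
    contrast = bundle$contrast),
    class = "twist_pipeline_report")
}

#' @export
print.twist_pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: %d records, %d of %d indicators selected\n",
              x$n_records, x$n_selected, x$n_indicators))
  cat("Top hubs:\n")
  print(x$hubs)
  if (length(x$event_path) > 0) {
    cat("Event <-> No_Event path: ",
        paste(x$event_path, collapse = " - "), "\n")
    cat(sprintf("%d node(s) reachable from Event without passing No_Event\n",
                length(x$event_side_nodes)))
  }
  if (x$meta_n_edges == 0) {
    cat("Meta-MST: no stable edges at threshold\n")
  } else {
    cat(sprintf("Meta-MST: %d stable edge(s)\n", x$meta_n_edges))
  }
  cat(sprintf("Group contrast (control - case): dH = %+.3f, dE_G = %+.3f\n",
              x$delta_H, x$delta_E_G))
  invisible(x)
}

#' @export
print.twist_pipeline <- function(x, ...) {
  cat(sprintf(
    "twist_pipeline: %d records, %d indicators%s, MST of %d nodes\n",
    nrow(x$cohort), x$manifest$n_indicators,
    if (is.na(x$manifest$n_selected %||% NA)) ""
    else sprintf(" (%d selected)", x$manifest$n_selected),
    length(x$mst$nodes)))
  invisible(x)
}
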