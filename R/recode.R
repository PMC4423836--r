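#' Assign tertile categories by rank
#'
#' Splits a numeric vector into three categories against the 1/3 and 2/3
#' empirical quantiles, so that continuous traits mirror the three genotype
#' classes. Category sizes are as equal as `n` permits; ties are broken by
#' original row order (stable, deterministic).
#'
#' @param values Numeric vector with at least 3 distinct values.
#' @return Integer vector in `{1, 2, 3}` (1 = lowest tertile).
#' @examples
#' tertile_bin(c(1, 2, 3, 4, 5, 6, 7, 8, 9))
#' @export
tertile_bin <- function(values) {
  if (anyNA(values)) {
    abort("tertile_bin() requires complete values.",
          class = "twistmap_error_recode")
  }
  n <- length(values)
  if (length(unique(values)) < 3) {
    abort("Cannot form tertiles: fewer than 3 distinct values.",
          class = "twistmap_error_recode")
  }
  r <- rank(values, ties.method = "first")
  as.integer(ceiling(3 * r / n))
}

#' Expand a cohort into binary indicator variables
#'
#' Recodes every schema variable into mutually exclusive, exhaustive binary
#' indicator columns: `genotype3` variables into their three genotype
#' classes, `continuous` variables into tertile membership (via
#' [tertile_bin()]), and `binary` variables into a no/yes pair. No reference
#' category is omitted. Optionally the binary outcome is appended as the
#' complementary pair `Event` / `No_Event`, so that presence and absence of
#' an event can enter the similarity network as two separate nodes.
#'
#' @param cohort Cohort tibble (see [read_cohort()], [generate_cohort()]).
#' @param schema Schema tibble; defaults to the cohort's `"schema"`
#'   attribute.
#' @param include_outcome Append `Event`/`No_Event` columns (default `TRUE`).
#' @return A tibble of 0/1 columns named `<variable>_<label>`, carrying an
#'   `"indicator_info"` attribute (see [indicator_info()]) that maps every
#'   column back to its parent variable and category.
#' @examples
#' sc <- cohort_schema(c("g"), "genotype3")
#' ch <- tibble::tibble(g = c(0, 1, 2, 1), outcome = c(1, 0, 1, 0))
#' expand_indicators(ch, sc)
#' @export
expand_indicators <- function(cohort, schema = attr(cohort, "schema"),
                              include_outcome = TRUE) {
  if (is.null(schema)) {
    abort("No schema supplied and cohort carries none.",
          class = "twistmap_error_recode")
  }
  cols <- list()
  info <- list()
  for (i in seq_len(nrow(schema))) {
    v <- schema$name[i]
    kind <- schema$kind[i]
    labels <- schema$labels[[i]]
    x <- cohort[[v]]
    cat <- switch(kind,
      continuous = tertile_bin(x),
      genotype3  = as.integer(x) + 1L,   # classes 1/2/3 from codes 0/1/2
      binary     = as.integer(x) + 1L    # 1 = no, 2 = yes
    )
    n_cat <- if (kind == "binary") 2L else 3L
    for (k in seq_len(n_cat)) {
      label <- paste(v, labels[k], sep = "_")
      cols[[label]] <- as.integer(cat == k)
      info[[label]] <- tibble(column = label, parent = v, category = k,
                              category_label = labels[k], role = "feature")
    }
  }
  if (include_outcome) {
    y <- as.integer(cohort$outcome)
    cols[["Event"]] <- y
    cols[["No_Event"]] <- 1L - y
    info[["Event"]] <- tibble(column = "Event", parent = ".outcome",
                              category = 2L, category_label = "yes",
                              role = "outcome")
    info[["No_Event"]] <- tibble(column = "No_Event", parent = ".outcome",
                                 category = 1L, category_label = "no",
                                 role = "outcome")
  }
  out <- as_tibble(cols)
  attr(out, "indicator_info") <- bind_rows(info)
  attr(out, "outcome") <- as.integer(cohort$outcome)
  out
}

#' Column metadata of an indicator matrix
#'
#' @param indicators Indicator tibble from [expand_indicators()].
#' @return Tibble with one row per indicator column: `column`, `parent`,
#'   `category` (1-based, low to high), `category_label`, and `role`
#'   (`"feature"` or `"outcome"`).
#' @export
indicator_info <- function(indicators) {
  info <- attr(indicators, "indicator_info")
  if (is.null(info)) {
    abort("Not an indicator matrix: no indicator_info attribute.",
          class = "twistmap_error_recode")
  }
  info
}

#' Feature columns of an indicator matrix, as a numeric matrix
#'
#' Drops outcome columns (`Event`/`No_Event`); downstream feature selection
#' must never evaluate the outcome as a feature.
#'
#' @param indicators Indicator tibble.
#' @return Numeric 0/1 matrix with indicator column names.
#' @export
feature_matrix <- function(indicators) {
  info <- indicator_info(indicators)
  keep <- info$column[info$role == "feature"]
  as.matrix(indicators[, keep, drop = FALSE])
}

#' Write an indicator matrix with its column metadata sidecar
#'
#' @param indicators Indicator tibble.
#' @param path Output CSV path for the 0/1 matrix.
#' @param meta_path Path for the JSON sidecar mapping columns to
#'   (parent, category); default `path` with extension `.meta.json`.
#' @return `path`, invisibly.
#' @export
write_indicators <- function(indicators, path, meta_path = NULL) {
  readr::write_csv(indicators, path, progress = FALSE)
  if (is.null(meta_path)) {
    meta_path <- paste0(sub("\\.[^.]+$", "", path), ".meta.json")
  }
  jsonlite::write_json(indicator_info(indicators), meta_path,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
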