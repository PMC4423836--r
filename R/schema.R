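#' Declare the variables of a cohort table
#'
#' A schema is a tibble with one row per analysis variable, declaring how the
#' column is typed and therefore how it will be recoded into binary indicator
#' variables: `continuous` traits are split into tertiles (three indicators),
#' `genotype3` variables carry the three genotype classes coded 0/1/2
#' (common homozygote / heterozygote / rare homozygote; three indicators),
#' and `binary` traits yield a no/yes indicator pair.
#'
#' @param name Character vector of variable names (cohort column names).
#' @param kind Character vector (recycled) in
#'   `c("continuous", "genotype3", "binary")`.
#' @param labels Optional list of character vectors of category labels, one
#'   per variable (3 labels for continuous/genotype3, 2 for binary, low to
#'   high). Defaults: tertiles `t1/t2/t3`, genotype classes `1/2/3`
#'   (1 = common homozygote), binary `no/yes`.
#'
#' @return A tibble with columns `name`, `kind` and list-column `labels`.
#' @examples
#' cohort_schema(c("bmi", "rs1234", "smoking"),
#'               c("continuous", "genotype3", "binary"))
#' @export
cohort_schema <- function(name, kind, labels = NULL) {
  kind <- rep_len(kind, length(name))
  bad <- setdiff(unique(kind), c("continuous", "genotype3", "binary"))
  if (length(bad) > 0) {
    abort(paste0("Unknown variable kind: ", paste(bad, collapse = ", ")),
          class = "twistmap_error_schema")
  }
  if (anyDuplicated(name)) {
    abort("Duplicate variable names in schema.",
          class = "twistmap_error_schema")
  }
  if (is.null(labels)) {
    labels <- lapply(kind, default_labels)
  } else {
    stopifnot(length(labels) == length(name))
    n_expect <- ifelse(kind == "binary", 2L, 3L)
    ok <- vapply(seq_along(labels), function(i) {
      length(labels[[i]]) == n_expect[i]
    }, logical(1))
    if (!all(ok)) {
      abort("Wrong number of category labels for variable kind.",
            class = "twistmap_error_schema")
    }
  }
  tibble(name = as.character(name), kind = kind, labels = labels)
}

default_labels <- function(kind) {
  switch(kind,
    continuous = c("t1", "t2", "t3"),
    genotype3  = c("1", "2", "3"),
    binary     = c("no", "yes")
  )
}

#' Read a variable schema from a YAML file
#'
#' The file holds a sequence of mappings, each with fields `name`, `kind`
#' and optionally `labels`:
#' ```yaml
#' - name: bmi
#'   kind: continuous
#' - name: rs1234
#'   kind: genotype3
#' ```
#'
#' @param path Path to a YAML schema file.
#' @return A schema tibble (see [cohort_schema()]).
#' @export
read_schema <- function(path) {
  spec <- yaml::read_yaml(path)
  if (length(spec) == 0) {
    abort("Empty schema file.", class = "twistmap_error_schema")
  }
  nm <- vapply(spec, function(v) v$name %||% NA_character_, character(1))
  kd <- vapply(spec, function(v) v$kind %||% NA_character_, character(1))
  lb <- lapply(spec, function(v) if (is.null(v$labels)) NULL else as.character(v$labels))
  if (all(vapply(lb, is.null, logical(1)))) {
    cohort_schema(nm, kd)
  } else {
    lb <- lapply(seq_along(lb), function(i) lb[[i]] %||% default_labels(kd[i]))
    cohort_schema(nm, kd, labels = lb)
  }
}

#' Write a schema tibble to YAML
#'
#' @param schema A schema tibble from [cohort_schema()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  spec <- lapply(seq_len(nrow(schema)), function(i) {
    list(name = schema$name[i], kind = schema$kind[i],
         labels = as.list(schema$labels[[i]]))
  })
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' Read a cohort table of individuals by typed variables
#'
#' Reads a delimited text file (comma or tab separated, header row, one row
#' per individual), checks it against a schema, and returns a typed cohort
#' tibble. Rows with a missing value in any schema variable or in the outcome
#' are dropped, with the number of removed records reported; the analysis is
#' restricted to complete records.
#'
#' @param path Path to a delimited text file.
#' @param schema Schema tibble from [cohort_schema()] or [read_schema()].
#' @param outcome Name of the binary outcome column (1 = event during
#'   follow-up), present in the file but not in the schema. Default
#'   `"outcome"`.
#' @return A tibble with the schema variables plus the outcome column, and a
#'   `"schema"` attribute. Genotype columns contain only 0/1/2.
#' @export
read_cohort <- function(path, schema, outcome = "outcome") {
  raw <- readr::read_delim(path, delim = sniff_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) {
    abort(paste0("Empty cohort file: ", path),
          class = "twistmap_error_cohort")
  }
  missing_cols <- setdiff(c(schema$name, outcome), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort file lacks declared column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "twistmap_error_cohort")
  }
  cohort <- raw[, c(schema$name, outcome)]
  names(cohort)[ncol(cohort)] <- "outcome"
  validate_cohort(cohort, schema, drop_incomplete = TRUE)
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) {
    abort(paste0("Empty cohort file: ", path), class = "twistmap_error_cohort")
  }
  if (grepl("\t", first)) "\t" else ","
}

#' Validate a cohort tibble against its schema
#'
#' @param cohort Tibble with the schema variables and an `outcome` column.
#' @param schema Schema tibble.
#' @param drop_incomplete Drop rows with missing values (reporting the count)
#'   rather than failing on them.
#' @return The validated cohort tibble with a `"schema"` attribute.
#' @export
validate_cohort <- function(cohort, schema, drop_incomplete = TRUE) {
  cohort <- as_tibble(cohort)
  complete <- stats::complete.cases(cohort[, c(schema$name, "outcome")])
  if (any(!complete)) {
    if (!drop_incomplete) {
      abort("Cohort contains missing values.", class = "twistmap_error_cohort")
    }
    inform(sprintf("%d record%s removed (incomplete phenotype/genotype data)",
                   sum(!complete), if (sum(!complete) == 1) "" else "s"))
    cohort <- cohort[complete, , drop = FALSE]
  }
  for (i in seq_len(nrow(schema))) {
    v <- schema$name[i]
    x <- cohort[[v]]
    if (schema$kind[i] == "genotype3" && !all(x %in% c(0, 1, 2))) {
      bad_row <- which(!(x %in% c(0, 1, 2)))[1]
      abort(sprintf(
        "Genotype column '%s' has value %s at row %d; expected 0/1/2.",
        v, format(x[bad_row]), bad_row),
        class = "twistmap_error_cohort")
    }
    if (schema$kind[i] == "binary" && !all(x %in% c(0, 1))) {
      abort(sprintf("Binary column '%s' must contain only 0/1.", v),
            class = "twistmap_error_cohort")
    }
  }
  if (!all(cohort$outcome %in% c(0, 1))) {
    abort("Outcome column must contain only 0/1.",
          class = "twistmap_error_cohort")
  }
  attr(cohort, "schema") <- schema
  cohort
}

#' Write a cohort tibble as delimited text
#'
#' Companion of [read_cohort()]; writes the cohort as CSV and, when the
#' cohort carries a schema attribute, the schema alongside as YAML.
#'
#' @param cohort Cohort tibble.
#' @param path Output CSV path.
#' @param schema_path Optional path for the YAML schema
#'   (default: `path` with extension `.schema.yaml`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, schema_path = NULL) {
  readr::write_csv(cohort, path, progress = FALSE)
  schema <- attr(cohort, "schema")
  if (!is.null(schema)) {
    if (is.null(schema_path)) {
      schema_path <- paste0(sub("\\.[^.]+$", "", path), ".schema.yaml")
    }
    write_schema(schema, schema_path)
  }
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
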