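#' @keywords internal
"_PACKAGE"

COLUMN_ROLES <- c("continuous", "date", "binary", "categorical", "identifier")

#' Declare a cohort column
#'
#' A column specification records how one variable of a cohort table is typed
#' and handled throughout the pipeline: its role (continuous measurement,
#' calendar date, binary/categorical code, or row identifier), its admissible
#' categories, whether it is considered sensitive for disclosure-risk
#' reporting, and which binning hierarchy (if any) anonymizes it.
#'
#' @param name Column name, unique within a configuration.
#' @param role One of `"continuous"`, `"date"`, `"binary"`, `"categorical"`,
#'   `"identifier"`.
#' @param units Free-text units (informational).
#' @param categories Character vector of admissible categories. Required for
#'   binary (exactly two) and categorical (at least one) roles; must be absent
#'   otherwise.
#' @param sensitive Logical flag marking the column sensitive.
#' @param binner Optional name of a binning hierarchy used by [adaptive_bin()].
#' @return An object of class `column_spec`.
#' @export
column_spec <- function(name, role, units = "", categories = NULL,
                        sensitive = FALSE, binner = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("column name must be a non-empty string")
  if (!role %in% COLUMN_ROLES)
    stop(sprintf("unknown role '%s' for column '%s'", role, name))
  if (role %in% c("binary", "categorical")) {
    if (is.null(categories) || length(categories) == 0L)
      stop(sprintf("column '%s' (%s) needs categories", name, role))
    if (role == "binary" && length(categories) != 2L)
      stop(sprintf("binary column '%s' must have exactly 2 categories", name))
    if (anyDuplicated(categories))
      stop(sprintf("duplicate categories in column '%s'", name))
  } else if (!is.null(categories)) {
    stop(sprintf("column '%s' (%s) must not declare categories", name, role))
  }
  structure(list(name = name, role = role, units = units,
                 categories = as.character(categories),
                 sensitive = isTRUE(sensitive),
                 binner = binner),
            class = "column_spec")
}

#' Assemble a study configuration
#'
#' The study configuration is the single declarative object that drives every
#' stage: the column schema, the missing-value marker used on disk, the
#' reference date for day-count encoding of calendar dates, the k-anonymity
#' threshold for aggregate views, loss weights for the correlation- and
#' distribution-aware objectives, match configurations for the heuristic
#' match-rate audit, constraint rules for rejection sampling, and the base
#' random seed.
#'
#' @param columns List of [column_spec()] objects.
#' @param reference_date Calendar date ("YYYY-MM-DD") that day counts are
#'   measured from.
#' @param k_anonymity Minimum group size for anonymized views; default 10 so
#'   no released aggregate can describe fewer than ten individuals.
#' @param missing_marker Token standing for a missing cell in delimited files.
#' @param loss_weights List with elements `alpha`, `beta`, `H`, `epsilon`; see
#'   [loss_weights()].
#' @param constraint_rules List of rule specifications; see [compile_rules()].
#' @param match_configs List of match configurations; see [match_config()].
#' @param hierarchies Named list of binning hierarchies (see
#'   [binner_hierarchy()]); merged over [builtin_hierarchies()].
#' @param seed Integer base seed; recorded so every derived artifact is
#'   reproducible.
#' @return An object of class `study_config`.
#' @export
study_config <- function(columns, reference_date = "2000-01-01",
                         k_anonymity = 10L, missing_marker = "n.a.",
                         loss_weights = NULL, constraint_rules = list(),
                         match_configs = list(), hierarchies = list(),
                         seed = 1L) {
  if (length(columns) == 0L) stop("a study_config needs at least one column")
  columns <- lapply(columns, function(cs) {
    if (!inherits(cs, "column_spec")) stop("columns must be column_spec objects")
    cs
  })
  nms <- vapply(columns, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop(sprintf("duplicate column name '%s'", nms[duplicated(nms)][1L]))
  names(columns) <- nms
  k_anonymity <- as.integer(k_anonymity)
  if (is.na(k_anonymity) || k_anonymity < 2L)
    stop("k_anonymity must be an integer >= 2")
  ref <- as.Date(reference_date)
  if (is.na(ref)) stop("reference_date must be an ISO-8601 date")
  lw <- make_loss_weights(loss_weights)
  for (rule in constraint_rules) {
    for (col in rule_columns(rule))
      if (!col %in% nms)
        stop(sprintf("constraint rule references undeclared column '%s'", col))
  }
  for (mc in match_configs) {
    for (col in names(mc$spans))
      if (!col %in% nms)
        stop(sprintf("match config references undeclared column '%s'", col))
  }
  structure(list(columns = columns, reference_date = ref,
                 k_anonymity = k_anonymity, missing_marker = missing_marker,
                 loss_weights = lw, constraint_rules = constraint_rules,
                 match_configs = match_configs, hierarchies = hierarchies,
                 seed = as.integer(seed)),
            class = "study_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rule_columns <- function(rule) {
  switch(rule$kind %||% "implication",
    implication = c(rule$if_column, rule$then_column),
    range = rule$column,
    dependency = c(rule$column_a, rule$column_b),
    stop(sprintf("unknown rule kind '%s'", rule$kind)))
}

#' @export
print.study_config <- function(x, ...) {
  roles <- vapply(x$columns, `[[`, character(1), "role")
  cat(sprintf("study_config: %d columns (%s), k=%d, marker '%s', seed %d\n",
              length(x$columns),
              paste(sprintf("%d %s", table(roles), names(table(roles))),
                    collapse = ", "),
              x$k_anonymity, x$missing_marker, x$seed))
  invisible(x)
}

#' Load a study configuration from YAML
#'
#' Parses and validates a configuration file. Missing optional fields are
#' filled with defaults: `k_anonymity` 10, `missing_marker` `"n.a."`,
#' `reference_date` 2000-01-01 and seed 1.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated [study_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  raw <- yaml::read_yaml(path)
  config_from_list(raw)
}

#' @rdname load_config
#' @param raw A list with the same structure as the YAML file.
#' @export
config_from_list <- function(raw) {
  if (is.null(raw$columns)) stop("config has no 'columns' section")
  cols <- lapply(raw$columns, function(c) {
    column_spec(name = c$name, role = c$role %||% stop("column without role"),
                units = c$units %||% "",
                categories = if (!is.null(c$categories)) as.character(c$categories),
                sensitive = isTRUE(c$sensitive), binner = c$binner)
  })
  study_config(columns = cols,
               reference_date = raw$reference_date %||% "2000-01-01",
               k_anonymity = raw$k_anonymity %||% 10L,
               missing_marker = raw$missing_marker %||% "n.a.",
               loss_weights = raw$loss_weights,
               constraint_rules = raw$constraint_rules %||% list(),
               match_configs = lapply(raw$match_configs %||% list(), function(m)
                 match_config(spans = m$spans, label = m$label %||% "")),
               hierarchies = lapply(raw$hierarchies %||% list(), hierarchy_from_list),
               seed = raw$seed %||% 1L)
}

#' Write a study configuration to YAML
#'
#' @param config A [study_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  out <- list(
    reference_date = format(config$reference_date),
    k_anonymity = config$k_anonymity,
    missing_marker = config$missing_marker,
    seed = config$seed,
    loss_weights = unclass(config$loss_weights),
    columns = lapply(unname(config$columns), function(cs) {
      c(list(name = cs$name, role = cs$role),
        if (nzchar(cs$units)) list(units = cs$units),
        if (length(cs$categories)) list(categories = as.list(cs$categories)),
        if (cs$sensitive) list(sensitive = TRUE),
        if (!is.null(cs$binner)) list(binner = cs$binner))
    }),
    constraint_rules = config$constraint_rules,
    match_configs = lapply(config$match_configs, function(m)
      list(label = m$label, spans = as.list(m$spans))))
  yaml::write_yaml(out, path)
  invisible(path)
}

role_of <- function(config, name) config$columns[[name]]$role

continuous_like <- function(config)
  names(config$columns)[vapply(config$columns, function(c)
    c$role %in% c("continuous", "date"), logical(1))]

categorical_like <- function(config)
  names(config$columns)[vapply(config$columns, function(c)
    c$role %in% c("binary", "categorical"), logical(1))]

#' Read a cohort table
#'
#' Reads a delimited text table (comma by default, tab autodetected) and types
#' every column per the configuration. Cells equal to the configured missing
#' marker (or empty) become `NA`; any other unparseable cell is an error that
#' names the offending row and column. Categorical cells outside the declared
#' categories are errors too.
#'
#' @param path Path to a delimited text file with a header row.
#' @param config A [study_config()] whose columns match the header exactly.
#' @return A typed `data.frame` (dates as `Date`, continuous as numeric,
#'   categorical/binary/identifier as character).
#' @export
read_cohort <- function(path, config) {
  stopifnot(inherits(config, "study_config"))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "\"",
                           stringsAsFactors = FALSE)
  declared <- names(config$columns)
  if (!identical(names(raw), declared))
    stop(sprintf("header mismatch: file has [%s], config declares [%s]",
                 paste(names(raw), collapse = ", "),
                 paste(declared, collapse = ", ")))
  typed_cohort(raw, config)
}

typed_cohort <- function(raw, config) {
  marker <- config$missing_marker
  out <- raw
  for (name in names(config$columns)) {
    cs <- config$columns[[name]]
    x <- raw[[name]]
    x[x == marker | x == ""] <- NA_character_
    out[[name]] <- switch(cs$role,
      continuous = {
        v <- suppressWarnings(as.numeric(x))
        bad <- which(is.na(v) & !is.na(x))
        if (length(bad))
          stop(sprintf("cannot parse '%s' as numeric (row %d, column '%s')",
                       x[bad[1L]], bad[1L], name))
        v
      },
      date = {
        v <- as.Date(x, format = "%Y-%m-%d")
        bad <- which(is.na(v) & !is.na(x))
        if (length(bad))
          stop(sprintf("cannot parse '%s' as ISO date (row %d, column '%s')",
                       x[bad[1L]], bad[1L], name))
        v
      },
      binary = ,
      categorical = {
        bad <- which(!is.na(x) & !x %in% cs$categories)
        if (length(bad))
          stop(sprintf("value '%s' outside declared categories (row %d, column '%s')",
                       x[bad[1L]], bad[1L], name))
        x
      },
      identifier = x)
  }
  out
}

#' Write a cohort table
#'
#' Inverse of [read_cohort()]: dates are formatted ISO-8601 and `NA` cells are
#' written as the configured missing marker, so read/write round-trips.
#'
#' @param cohort A typed cohort `data.frame`.
#' @param path Output path.
#' @param config A [study_config()].
#' @param sep Field separator (`","` default).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, config, sep = ",") {
  out <- cohort
  for (name in names(config$columns)) {
    x <- cohort[[name]]
    if (inherits(x, "Date")) x <- format(x, "%Y-%m-%d")
    x <- as.character(x)
    x[is.na(x)] <- config$missing_marker
    out[[name]] <- x
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a cohort against its schema
#'
#' Reports (never raises) per-column violations — categorical cells outside
#' the declared categories, dates outside plausible bounds — and a structural
#' check that the column names match the configuration. Mirrors a diagnostic
#' report: data validity verifies that values are within the correct
#' ranges or category options, data structure verifies shape and names.
#'
#' @param cohort A cohort `data.frame` (possibly from an external generator).
#' @param config A [study_config()].
#' @param reference An optional reference cohort supplying numeric ranges;
#'   when given, continuous/date cells outside the reference min/max are
#'   counted as range violations.
#' @return A list of class `validation_report` with elements `violations`
#'   (data.frame of row/column/value), `n_violations`, `structure_ok`,
#'   `structure_score` (1 if names and order match, else fraction of declared
#'   columns present), `validity_score` (fraction of checked cells without
#'   violation).
#' @export
validate_table <- function(cohort, config, reference = NULL) {
  declared <- names(config$columns)
  present <- intersect(declared, names(cohort))
  structure_ok <- identical(names(cohort), declared)
  structure_score <- if (structure_ok) 1 else length(present) / length(declared)
  viol <- list()
  checked <- 0L
  for (name in present) {
    cs <- config$columns[[name]]
    x <- cohort[[name]]
    checked <- checked + sum(!is.na(x))
    bad <- integer(0)
    if (cs$role %in% c("binary", "categorical")) {
      bad <- which(!is.na(x) & !as.character(x) %in% cs$categories)
    } else if (cs$role %in% c("continuous", "date") && !is.null(reference) &&
               name %in% names(reference)) {
      r <- reference[[name]]
      lo <- suppressWarnings(min(r, na.rm = TRUE))
      hi <- suppressWarnings(max(r, na.rm = TRUE))
      bad <- which(!is.na(x) & (x < lo | x > hi))
    }
    if (length(bad))
      viol[[name]] <- data.frame(row = bad, column = name,
                                 value = as.character(x[bad]),
                                 stringsAsFactors = FALSE)
  }
  violations <- if (length(viol)) do.call(rbind, c(viol, make.row.names = FALSE))
                else data.frame(row = integer(0), column = character(0),
                                value = character(0), stringsAsFactors = FALSE)
  structure(list(violations = violations, n_violations = nrow(violations),
                 structure_ok = structure_ok, structure_score = structure_score,
                 validity_score = if (checked) 1 - nrow(violations) / checked else 1,
                 missing_columns = setdiff(declared, names(cohort)),
                 extra_columns = setdiff(names(cohort), declared)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation: %d violation(s), structure %s (score %.3f)\n",
              x$n_violations, if (x$structure_ok) "ok" else "FAILED",
              x$structure_score))
  invisible(x)
}

#' Serialize a report to JSON
#'
#' Writes any report list as JSON with stable key ordering so reports diff
#' cleanly across runs.
#'
#' @param report A named list (a validation, privacy, similarity or rejection
#'   report).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(strip_classes(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, strip_classes)
  }
  if (!is.data.frame(x)) attr(x, "class") <- NULL
  x
}
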