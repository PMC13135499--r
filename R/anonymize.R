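#' Binning hierarchies for adaptive anonymization
#'
#' A hierarchy lists coarse-graining levels for one attribute, finest first.
#' Each level partitions the attribute's domain exhaustively: numeric
#' ("interval") levels are half-open `[lo, hi)` intervals given by breaks and
#' labels, categorical ("group") levels map labels to sets of raw values.
#' Missing values always form their own `"missing"` bin at every level, so no
#' row is ever dropped from a released count.
#'
#' @param attribute Attribute (column) name.
#' @param levels List of levels, finest to coarsest. An interval level is
#'   `list(type = "interval", breaks = c(-Inf, ..., Inf), labels = ...)`
#'   (one more break than labels); a group level is
#'   `list(type = "group", groups = list(label = c(values...)))`.
#' @return An object of class `binner_hierarchy`.
#' @export
binner_hierarchy <- function(attribute, levels) {
  for (lv in levels) {
    if (identical(lv$type, "interval")) {
      if (length(lv$breaks) != length(lv$labels) + 1L)
        stop(sprintf("hierarchy '%s': breaks/labels mismatch", attribute))
      if (is.unsorted(lv$breaks, strictly = TRUE))
        stop(sprintf("hierarchy '%s': breaks must be strictly increasing", attribute))
    } else if (!identical(lv$type, "group")) {
      stop("level type must be 'interval' or 'group'")
    }
  }
  structure(list(attribute = attribute, levels = levels),
            class = "binner_hierarchy")
}

hierarchy_from_list <- function(raw) {
  binner_hierarchy(raw$attribute, lapply(raw$levels, function(lv) {
    if (identical(lv$type, "interval"))
      list(type = "interval", breaks = as.numeric(unlist(lv$breaks)),
           labels = as.character(unlist(lv$labels)))
    else list(type = "group", groups = lapply(lv$groups, as.character))
  }))
}

#' Apply one hierarchy level to raw values
#'
#' @param values Raw attribute values.
#' @param level One level of a [binner_hierarchy()].
#' @return Character bin labels; missing values become `"missing"`.
#' @export
apply_binner_level <- function(values, level) {
  out <- rep("missing", length(values))
  ok <- !is.na(values)
  if (identical(level$type, "interval")) {
    v <- as.numeric(values[ok])
    idx <- findInterval(v, level$breaks, rightmost.closed = FALSE,
                        left.open = FALSE)
    idx[idx < 1L] <- 1L
    idx[idx > length(level$labels)] <- length(level$labels)
    out[ok] <- level$labels[idx]
  } else {
    v <- as.character(values[ok])
    map <- rep(NA_character_, 0)
    for (lab in names(level$groups))
      map[level$groups[[lab]]] <- lab
    hit <- map[v]
    hit[is.na(hit)] <- "other"
    out[ok] <- hit
  }
  out
}

#' Built-in clinical binning hierarchies
#'
#' Two ready-made hierarchies: birth year (decades with adapted tails —
#' "<1940", "1940s", "1950s", "1960+" — coarsening to "<1950" / "1950+") and
#' BMI (the clinical classes underweight `[,18.5)`, normal `[18.5, 25)`,
#' overweight `[25, 30)`, obesity `[30,)`, coarsening to "normal-" /
#' "overweight+" with the cut at 25). All intervals are half-open `[lo, hi)`.
#'
#' @return Named list of [binner_hierarchy()] objects (`birth_year`, `bmi`).
#' @export
builtin_hierarchies <- function() {
  list(
    birth_year = binner_hierarchy("birth_year", list(
      list(type = "interval",
           breaks = c(-Inf, 1940, 1950, 1960, Inf),
           labels = c("<1940", "1940s", "1950s", "1960+")),
      list(type = "interval",
           breaks = c(-Inf, 1950, Inf),
           labels = c("<1950", "1950+")))),
    bmi = binner_hierarchy("bmi", list(
      list(type = "interval",
           breaks = c(-Inf, 18.5, 25, 30, Inf),
           labels = c("underweight", "normal", "overweight", "obesity")),
      list(type = "interval",
           breaks = c(-Inf, 25, Inf),
           labels = c("normal-", "overweight+")))))
}

#' Globally rarest value of a binned table
#'
#' Scans every remaining column for its least frequent value and returns the
#' (column, value) pair with the globally smallest count. Ties are broken
#' deterministically: first by column order, then by sorted bin label. With no
#' columns left, the column is `NA` and the count is the table size.
#'
#' @param table A data.frame of bin labels (character columns).
#' @return `list(column, value, count)`.
#' @export
greedy_filter <- function(table) {
  best <- list(column = NA_character_, value = NA_character_,
               count = nrow(table))
  for (cn in names(table)) {
    tab <- base::table(table[[cn]])
    tab <- tab[order(names(tab))]
    j <- which.min(tab)
    # strict improvement keeps the first column on ties; a constant single
    # column (count == table size) is still reported so callers can act on it
    if (tab[j] < best$count ||
        (is.na(best$column) && tab[j] == best$count)) {
      best <- list(column = cn, value = names(tab)[j],
                   count = as.integer(tab[j]))
    }
  }
  best
}

#' Greedy total-k-anonymity test
#'
#' Fast necessary check: repeatedly restrict the table to the rows carrying
#' the globally rarest value and drop that column; fail as soon as any
#' encountered count is below `k`, succeed when columns are exhausted. A
#' `FALSE` here is definitive (some filter chain isolates fewer than `k`
#' rows); a `TRUE` must still be confirmed by the exhaustive test.
#'
#' @param table A data.frame of bin labels.
#' @param k Minimum group size (>= 2).
#' @return Logical.
#' @export
greedy_privacy_test <- function(table, k) {
  stopifnot(k >= 2)
  D <- table
  while (ncol(D) > 0L) {
    f <- greedy_filter(D)
    if (is.na(f$column)) return(TRUE)
    if (f$count < k) return(FALSE)
    D <- D[D[[f$column]] == f$value, setdiff(names(D), f$column), drop = FALSE]
  }
  TRUE
}

#' Exhaustive total-k-anonymity test
#'
#' Recursive ground truth: the table is totally k-anonymous iff every nested
#' sequence of single-value filters over distinct columns leaves at least `k`
#' rows at every step. States are memoized on the sorted filter assignment;
#' exceeding the state budget raises an error rather than passing silently.
#'
#' @param table A data.frame of bin labels.
#' @param k Minimum group size (>= 2).
#' @param max_states Cap on explored filter states (default 1e6).
#' @return Logical.
#' @export
brute_force_privacy_test <- function(table, k, max_states = 1e6) {
  stopifnot(k >= 2)
  env <- new.env(parent = emptyenv())
  env$states <- 0L
  env$memo <- new.env(parent = emptyenv())
  recurse <- function(D, filters) {
    key <- paste0("k:", paste(sort(filters), collapse = "|"))
    hit <- get0(key, envir = env$memo)
    if (!is.null(hit)) return(hit)
    env$states <- env$states + 1L
    if (env$states > max_states)
      stop("brute-force privacy check exceeded its state budget")
    res <- TRUE
    for (cn in names(D)) {
      for (v in unique(D[[cn]])) {
        rows <- D[[cn]] == v
        if (sum(rows) < k) { res <- FALSE; break }
        if (!recurse(D[rows, setdiff(names(D), cn), drop = FALSE],
                     c(filters, paste0(cn, "=", v)))) { res <- FALSE; break }
      }
      if (!res) break
    }
    assign(key, res, envir = env$memo)
    res
  }
  recurse(table, character(0))
}

#' Combined privacy verification
#'
#' Runs the greedy test first and, only if it passes, confirms with the
#' exhaustive test; the result always equals the exhaustive truth.
#'
#' @inheritParams brute_force_privacy_test
#' @param instrument If `TRUE`, return a list with the result and which tests
#'   ran (used to verify short-circuiting).
#' @return Logical (or an instrumented list).
#' @export
privacy_satisfied <- function(table, k, max_states = 1e6, instrument = FALSE) {
  ok <- greedy_privacy_test(table, k)
  ran_bf <- FALSE
  if (ok) {
    ok <- brute_force_privacy_test(table, k, max_states)
    ran_bf <- TRUE
  }
  if (instrument) list(ok = ok, brute_force_ran = ran_bf) else ok
}

#' Adaptive binning to total k-anonymity
#'
#' Bins the selected attributes at their finest hierarchy level and then,
#' while the verified total-k-anonymity property fails, coarsens the column
#' flagged by [greedy_filter()] by one level — or removes it when no coarser
#' level exists (columns without a hierarchy can only be removed). Terminates
#' because levels are finite; in the worst case all columns are removed and
#' the empty schema is trivially private.
#'
#' @param cohort A cohort data.frame.
#' @param k Minimum group size.
#' @param hierarchies Named list of [binner_hierarchy()] objects, keyed by
#'   column name. Columns listed in `columns` without a hierarchy are used at
#'   their raw values.
#' @param columns Columns to include in the released view (default: hierarchy
#'   columns plus none).
#' @param max_states Budget for the exhaustive verifier.
#' @return A list of class `anonymized_table`: `table` (bin labels), `levels`
#'   (final level index per surviving column), `removed` (columns dropped),
#'   `k`, `iterations`.
#' @export
adaptive_bin <- function(cohort, k, hierarchies = builtin_hierarchies(),
                         columns = names(hierarchies), max_states = 1e6) {
  stopifnot(k >= 2)
  columns <- intersect(columns, names(cohort))
  if (!length(columns)) stop("no columns to anonymize")
  level_idx <- stats::setNames(rep(1L, length(columns)), columns)
  bin_col <- function(cn, lvl) {
    h <- hierarchies[[cn]]
    if (is.null(h)) {
      v <- as.character(cohort[[cn]])
      v[is.na(v)] <- "missing"
      v
    } else apply_binner_level(cohort[[cn]], h$levels[[lvl]])
  }
  D <- as.data.frame(lapply(columns, function(cn) bin_col(cn, 1L)),
                     col.names = columns, stringsAsFactors = FALSE)
  removed <- character(0)
  iterations <- 0L
  repeat {
    if (ncol(D) == 0L || privacy_satisfied(D, k, max_states)) break
    iterations <- iterations + 1L
    f <- greedy_filter(D)
    cn <- f$column
    h <- hierarchies[[cn]]
    if (!is.null(h) && level_idx[[cn]] < length(h$levels)) {
      level_idx[[cn]] <- level_idx[[cn]] + 1L
      D[[cn]] <- bin_col(cn, level_idx[[cn]])
    } else {
      D[[cn]] <- NULL
      removed <- c(removed, cn)
      level_idx <- level_idx[setdiff(names(level_idx), cn)]
    }
  }
  structure(list(table = D, levels = level_idx, removed = removed,
                 k = k, iterations = iterations),
            class = "anonymized_table")
}

#' @export
print.anonymized_table <- function(x, ...) {
  cat(sprintf("anonymized_table: %d rows, %d columns (k=%d, %d coarsening step(s), removed: %s)\n",
              nrow(x$table), ncol(x$table), x$k, x$iterations,
              if (length(x$removed)) paste(x$removed, collapse = ", ") else "none"))
  invisible(x)
}

#' Count individuals matching a filter on an anonymized view
#'
#' Exact counts over a verified table: by construction of total k-anonymity,
#' every nonzero count returned is at least `k`.
#'
#' @param anonymized An `anonymized_table` from [adaptive_bin()].
#' @param filter Named character vector/list, `column = bin label`,
#'   interpreted as a conjunction. Empty filter counts all rows.
#' @return Integer count.
#' @export
aggregate_counts <- function(anonymized, filter = list()) {
  D <- anonymized$table
  if (!length(filter)) return(nrow(D))
  for (cn in names(filter)) {
    if (!cn %in% names(D))
      stop(sprintf("filter on removed or unknown column '%s'", cn))
    D <- D[D[[cn]] == filter[[cn]], , drop = FALSE]
  }
  nrow(D)
}
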