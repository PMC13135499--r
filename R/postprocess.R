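# Constraint-driven postprocessing: expert-defined logical and statistical
# rules enforced on generated cohorts by rejection sampling. Rules come from
# configuration, never from the real records, so applying them does not touch
# private training data.

#' Compile declarative constraint rules
#'
#' Turns rule specifications into executable predicates. Three kinds:
#' * `implication` — row-level: if `if_column` compares true against
#'   `if_value`, then `then_column` must compare true against `then_value`
#'   (comparators: `==`, `!=`, `in`, `not_in`, `<`, `<=`, `>`, `>=`).
#' * `range` — row-level: `column` within `[lo, hi]`.
#' * `dependency` — batch-level: `|cor(column_a, column_b) - target| <= tol`
#'   on the accepted batch.
#' A missing value in a row-level antecedent (or range operand) satisfies the
#' rule vacuously: rejecting on missing would silently bias missingness.
#'
#' @param rule_specs List of rule spec lists, e.g.
#'   `list(kind = "implication", if_column = "sex", if_op = "==",
#'   if_value = "male", then_column = "cancer_type", then_op = "not_in",
#'   then_value = c("cervical"), name = "no-male-cervical")`.
#' @param config A [study_config()]; rules may only reference declared
#'   columns.
#' @return A list of class `constraint_rules`.
#' @export
compile_rules <- function(rule_specs, config) {
  declared <- names(config$columns)
  rules <- lapply(seq_along(rule_specs), function(i) {
    spec <- rule_specs[[i]]
    kind <- spec$kind %||% "implication"
    for (col in rule_columns(c(spec, list(kind = kind))))
      if (!col %in% declared)
        stop(sprintf("rule %d references undeclared column '%s'", i, col))
    name <- spec$name %||% sprintf("rule_%d", i)
    switch(kind,
      implication = {
        if_op <- match_comparator(spec$if_op %||% "==")
        then_op <- match_comparator(spec$then_op %||% "==")
        list(kind = "implication", name = name, severity = "reject_row",
             predicate = local({
               ic <- spec$if_column; iv <- spec$if_value
               tc <- spec$then_column; tv <- spec$then_value
               function(batch) {
                 ante <- if_op(batch[[ic]], iv)
                 cons <- then_op(batch[[tc]], tv)
                 # vacuous on missing antecedent or consequent operand
                 !ifelse(is.na(ante), FALSE, ante) |
                   ifelse(is.na(cons), TRUE, cons)
               }
             }))
      },
      range = {
        list(kind = "range", name = name, severity = "reject_row",
             predicate = local({
               cn <- spec$column; lo <- spec$lo; hi <- spec$hi
               function(batch) {
                 v <- as.numeric(batch[[cn]])
                 is.na(v) | (v >= lo & v <= hi)
               }
             }))
      },
      dependency = {
        if (is.null(spec$tol) || spec$tol <= 0)
          stop(sprintf("rule %d: dependency rules need tol > 0", i))
        list(kind = "dependency", name = name, severity = "reject_batch",
             columns = c(spec$column_a, spec$column_b),
             target = spec$target, tol = spec$tol,
             predicate = local({
               ca <- spec$column_a; cb <- spec$column_b
               tg <- spec$target; tol <- spec$tol
               function(batch) {
                 a <- as.numeric(batch[[ca]]); b <- as.numeric(batch[[cb]])
                 ok <- stats::complete.cases(a, b)
                 if (sum(ok) < 3L) return(TRUE)
                 abs(suppressWarnings(stats::cor(a[ok], b[ok])) - tg) <= tol
               }
             }))
      },
      stop(sprintf("unknown rule kind '%s'", kind)))
  })
  structure(rules, class = "constraint_rules")
}

match_comparator <- function(op) {
  switch(op,
    "==" = function(x, v) as.character(x) == as.character(v),
    "!=" = function(x, v) as.character(x) != as.character(v),
    "in" = function(x, v) as.character(x) %in% as.character(v) &
                          !is.na(x),
    "not_in" = function(x, v) ifelse(is.na(x), NA,
                                     !as.character(x) %in% as.character(v)),
    "<" = function(x, v) as.numeric(x) < v,
    "<=" = function(x, v) as.numeric(x) <= v,
    ">" = function(x, v) as.numeric(x) > v,
    ">=" = function(x, v) as.numeric(x) >= v,
    stop(sprintf("unknown comparator '%s'", op)))
}

#' Default oncology rule pack
#'
#' Implication rules encoding sex-specific malignancies: cervical, placental,
#' endometrial and ovarian cancers occur only in females; prostate and
#' testicular cancers only in males.
#'
#' @param sex_column Sex column name.
#' @param cancer_column Cancer-type column name.
#' @param female,male Labels of the two sexes.
#' @return A list of rule specs for [compile_rules()].
#' @export
oncology_rule_pack <- function(sex_column = "sex",
                               cancer_column = "cancer_type",
                               female = "female", male = "male") {
  female_only <- c("cervical", "placental", "endometrial", "ovarian")
  male_only <- c("prostate", "testicular")
  list(
    list(kind = "implication", name = "female_only_cancers",
         if_column = sex_column, if_op = "==", if_value = male,
         then_column = cancer_column, then_op = "not_in",
         then_value = female_only),
    list(kind = "implication", name = "male_only_cancers",
         if_column = sex_column, if_op = "==", if_value = female,
         then_column = cancer_column, then_op = "not_in",
         then_value = male_only))
}

#' Row acceptance mask for a batch
#'
#' Evaluates all row-level rules on a batch; a row is accepted iff every rule
#' holds.
#'
#' @param batch A cohort `data.frame`.
#' @param rules A `constraint_rules` object.
#' @return List with `mask` (logical), `rejections` (named per-rule counts).
#' @export
accept_mask <- function(batch, rules) {
  mask <- rep(TRUE, nrow(batch))
  rejections <- integer(0)
  for (rule in rules) {
    if (!identical(rule$severity, "reject_row")) next
    ok <- rule$predicate(batch)
    ok[is.na(ok)] <- TRUE
    rejections[[rule$name]] <- sum(!ok)
    mask <- mask & ok
  }
  list(mask = mask, rejections = rejections)
}

#' Rejection sampling to a target size
#'
#' Draws batches from the generator, filters rows through the row-level
#' rules, and repeats until `n_target` accepted rows exist, over-generating
#' each round by the inverse of the observed acceptance rate (floored at 0.1)
#' to bound the number of iterations. Batch-level dependency rules are
#' re-checked on the final accepted set. If the target cannot be reached
#' within `max_iter` iterations an error is raised carrying the partial log —
#' never a silently undersized cohort.
#'
#' @param generate Function `(n, seed)` returning a conforming batch.
#' @param rules A `constraint_rules` object.
#' @param n_target Rows required.
#' @param max_iter Iteration budget (>= 1).
#' @param seed Integer seed; iteration `i` uses `seed + i`.
#' @return List with `cohort` (exactly `n_target` rows), `log` (a
#'   `rejection_log`: per-rule counts, iterations, acceptance rate,
#'   batch-rule results).
#' @export
rejection_sample <- function(generate, rules, n_target, max_iter = 50L,
                             seed = 1L) {
  stopifnot(max_iter >= 1L)
  accepted <- NULL
  produced <- 0L
  kept <- 0L
  rejections <- integer(0)
  iter <- 0L
  while (is.null(accepted) || nrow(accepted) < n_target) {
    if (iter >= max_iter) {
      log <- rejection_log(rejections, iter, kept, produced, list())
      stop(structure(class = c("rejection_infeasible", "error", "condition"),
                     list(message = sprintf(
                       "rejection sampling infeasible: %d/%d rows after %d iteration(s)",
                       kept, n_target, iter),
                       call = sys.call(), log = log)))
    }
    iter <- iter + 1L
    deficit <- n_target - kept
    rate <- if (produced > 0L) max(kept / produced, 0.1) else 1
    n_draw <- min(ceiling(deficit / rate), 10L * n_target)
    batch <- generate(n_draw, seed + iter)
    res <- accept_mask(batch, rules)
    produced <- produced + nrow(batch)
    for (nm in names(res$rejections)) {
      prev <- if (nm %in% names(rejections)) rejections[[nm]] else 0L
      rejections[[nm]] <- prev + res$rejections[[nm]]
    }
    keep <- batch[res$mask, , drop = FALSE]
    accepted <- if (is.null(accepted)) keep else rbind(accepted, keep)
    kept <- nrow(accepted)
  }
  out <- accepted[seq_len(n_target), , drop = FALSE]
  rownames(out) <- NULL
  batch_results <- list()
  for (rule in rules) {
    if (identical(rule$severity, "reject_batch"))
      batch_results[[rule$name]] <- isTRUE(rule$predicate(out))
  }
  list(cohort = out,
       log = rejection_log(rejections, iter, kept, produced, batch_results))
}

rejection_log <- function(rejections, iterations, kept, produced,
                          batch_results) {
  structure(list(rejections = as.list(rejections), iterations = iterations,
                 accepted = kept, produced = produced,
                 acceptance_rate = if (produced > 0) kept / produced else NA_real_,
                 batch_rules = batch_results),
            class = "rejection_log")
}

#' @export
print.rejection_log <- function(x, ...) {
  cat(sprintf("rejection_log: %d/%d rows accepted (rate %.3f) in %d iteration(s)\n",
              x$accepted, x$produced, x$acceptance_rate, x$iterations))
  invisible(x)
}
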