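# Pipeline orchestration: prepare -> generate -> postprocess -> evaluate ->
# privacy -> rank, with a reproducible run manifest per released artifact.

#' Run the end-to-end synthesis pipeline
#'
#' Executes the staged workflow on a cohort: level-3 preprocessing, synthetic
#' generation (Gaussian-copula baseline and, optionally, a loss-refined
#' variant), constraint postprocessing, similarity evaluation, privacy
#' evaluation, and a Friedman/Nemenyi ranking of the candidate generators.
#' Each stage writes a JSON report into `out_dir`; a run manifest records the
#' config hash, seeds, package version, per-artifact digests and timestamps.
#' The synthetic cohort is only copied into `out_dir/released/` when the
#' quality gate passes.
#'
#' @param cohort A typed cohort `data.frame` (or a path readable by
#'   [read_cohort()]).
#' @param config A [study_config()] or path to one.
#' @param out_dir Output directory (created).
#' @param stages Subset of
#'   `c("preprocess", "synthesize", "postprocess", "evaluate", "privacy",
#'   "rank")`; later stages depend on earlier ones.
#' @param n_synth Synthetic rows to generate (default `nrow(cohort)`).
#' @param refine_steps Refinement steps for the second candidate generator
#'   (0 disables it and the ranking stage compares copula seeds instead).
#' @param gate_thresholds Thresholds for [quality_gate()]; `NULL` leaves the
#'   gate unconstrained (flagged in the manifest).
#' @param seed Integer seed (defaults to the config's).
#' @return A list of class `run_manifest` (invisibly written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(cohort, config, out_dir,
                         stages = c("preprocess", "synthesize", "postprocess",
                                    "evaluate", "privacy", "rank"),
                         n_synth = NULL, refine_steps = 0L,
                         gate_thresholds = NULL, seed = NULL) {
  if (is.character(config)) config <- load_config(config)
  if (is.character(cohort)) cohort <- read_cohort(cohort, config)
  if (is.null(seed)) seed <- config$seed
  if (is.null(n_synth)) n_synth <- nrow(cohort)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  order_ <- c("preprocess", "synthesize", "postprocess", "evaluate",
              "privacy", "rank")
  stages <- order_[order_ %in% stages]
  manifest <- list(package_version = as.character(utils::packageVersion("tabsafe")),
                   seed = seed, stages = stages, started = format(Sys.time()),
                   artifacts = list(), stage_status = list())
  art <- function(name, path) {
    manifest$artifacts[[name]] <<- list(path = basename(path),
                                        md5 = unname(tools::md5sum(path)))
  }
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, fn) {
    ok <- tryCatch({ fn(); TRUE },
                   error = function(e) {
                     manifest$stage_status[[name]] <<-
                       list(ok = FALSE, error = conditionMessage(e))
                     FALSE
                   })
    if (ok) manifest$stage_status[[name]] <- list(ok = TRUE)
    if (!ok) {
      manifest$finished <- format(Sys.time())
      write_report(manifest, file.path(out_dir, "manifest.json"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   manifest$stage_status[[name]]$error))
    }
    manifest
  }

  if ("preprocess" %in% stages) manifest <- run_stage("preprocess", function() {
    state$enc <- fit_transform(cohort, config)
    p <- file.path(out_dir, "encoded_matrix.csv")
    utils::write.csv(state$enc$matrix, p, row.names = FALSE)
    art("encoded_matrix", p)
  })
  if ("synthesize" %in% stages) manifest <- run_stage("synthesize", function() {
    gen <- function(n, s) {
      mat <- copula_baseline_sample(state$enc$matrix, n, s)
      inverse_transform(mat, state$enc$transform, config)
    }
    state$generate <- gen
    state$synth <- gen(n_synth, seed)
    if (refine_steps > 0L) {
      mat <- copula_baseline_sample(state$enc$matrix, n_synth, seed + 1L)
      mat <- refine_synthetic(mat, state$enc$matrix, config$loss_weights,
                              steps = refine_steps, seed = seed + 1L)
      state$synth_refined <- inverse_transform(mat, state$enc$transform, config)
    }
    p <- file.path(out_dir, "synthetic_raw.csv")
    write_cohort(state$synth, p, config)
    art("synthetic_raw", p)
  })
  if ("postprocess" %in% stages) manifest <- run_stage("postprocess", function() {
    rules <- compile_rules(config$constraint_rules, config)
    if (length(rules)) {
      rs <- rejection_sample(state$generate, rules, n_synth,
                             max_iter = 50L, seed = seed)
      state$synth <- rs$cohort
      state$rejection <- rs$log
    } else {
      state$rejection <- rejection_log(integer(0), 1L, n_synth, n_synth, list())
    }
    p <- file.path(out_dir, "rejection.json")
    write_report(state$rejection, p)
    art("rejection_log", p)
    p2 <- file.path(out_dir, "synthetic_final.csv")
    write_cohort(state$synth, p2, config)
    art("synthetic_final", p2)
  })
  if ("evaluate" %in% stages) manifest <- run_stage("evaluate", function() {
    state$similarity <- similarity_report(cohort, state$synth, config)
    rep_ <- state$similarity
    rep_$correlation_difference <- NULL
    rep_$per_column <- lapply(rep_$per_column, `[[`, "score")
    p <- file.path(out_dir, "evaluate.json")
    write_report(rep_, p)
    art("similarity_report", p)
  })
  if ("privacy" %in% stages) manifest <- run_stage("privacy", function() {
    enc_s <- encode_with(state$synth, state$enc$transform, config)
    state$privacy <- privacy_report(state$enc$matrix, enc_s, seed = seed)
    p <- file.path(out_dir, "privacy.json")
    write_report(state$privacy, p)
    art("privacy_report", p)
  })
  if ("rank" %in% stages) manifest <- run_stage("rank", function() {
    cands <- list(copula = state$synth)
    if (!is.null(state$synth_refined)) cands$refined <- state$synth_refined
    else cands$copula_alt <- {
      mat <- copula_baseline_sample(state$enc$matrix, n_synth, seed + 2L)
      inverse_transform(mat, state$enc$transform, config)
    }
    fam <- score_candidates(cohort, cands, config)
    state$ranks <- aggregate_rankings(fam)
    p <- file.path(out_dir, "ranks.json")
    write_report(list(average_ranks = as.list(state$ranks$average_ranks),
                      critical_difference = state$ranks$overall$critical_difference),
                 p)
    art("rank_table", p)
  })

  gate <- quality_gate(list(similarity = state$similarity,
                            privacy = state$privacy),
                       gate_thresholds)
  manifest$quality_gate <- gate
  if (gate$pass && !is.null(state$synth)) {
    rel <- file.path(out_dir, "released")
    dir.create(rel, showWarnings = FALSE)
    p <- file.path(rel, "synthetic.csv")
    write_cohort(state$synth, p, config)
    art("released_synthetic", p)
  }
  manifest$finished <- format(Sys.time())
  class(manifest) <- "run_manifest"
  write_report(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

score_candidates <- function(real, candidates, config) {
  stat <- vapply(candidates, function(s) {
    rep_ <- similarity_report(real, s, config)
    c(rep_$column_shapes, rep_$pair_trends)
  }, numeric(2))
  enc_r <- fit_transform(real, config)
  priv <- vapply(candidates, function(s) {
    enc_s <- encode_with(s, enc_r$transform, config)
    1 - identifiability_score(enc_r$matrix, enc_s)$score
  }, numeric(1))
  dimnames(stat) <- list(NULL, names(candidates))
  list(statistical = stat,
       privacy = base::matrix(priv, nrow = 1,
                              dimnames = list(NULL, names(candidates))))
}

#' Quality gate over stage reports
#'
#' Boolean gate evaluated on declared report fields. Each threshold names a
#' dotted report field, a comparator and a bound, e.g.
#' `list(field = "similarity.quality_score", op = ">=", value = 0.8)`. With
#' no thresholds the gate passes but is flagged unconstrained — human review
#' is never auto-passed silently.
#'
#' @param reports Named list of reports (e.g. `similarity`, `privacy`).
#' @param thresholds List of threshold specs, or `NULL`.
#' @return List with `pass`, `reasons` (failing criteria), `unconstrained`.
#' @export
quality_gate <- function(reports, thresholds = NULL) {
  if (is.null(thresholds) || !length(thresholds))
    return(list(pass = TRUE, reasons = list(), unconstrained = TRUE))
  reasons <- list()
  for (th in thresholds) {
    val <- extract_field(reports, th$field)
    if (is.null(val) || !is.numeric(val))
      stop(sprintf("quality gate references unknown report field '%s'", th$field))
    ok <- switch(th$op, ">=" = val >= th$value, "<=" = val <= th$value,
                 ">" = val > th$value, "<" = val < th$value,
                 stop(sprintf("unknown gate comparator '%s'", th$op)))
    if (!ok) reasons[[length(reasons) + 1L]] <-
        sprintf("%s = %.4f violates %s %s", th$field, val, th$op,
                format(th$value))
  }
  list(pass = !length(reasons), reasons = reasons, unconstrained = FALSE)
}

extract_field <- function(x, field) {
  for (part in strsplit(field, ".", fixed = TRUE)[[1L]]) {
    if (!is.list(x) || is.null(x[[part]])) return(NULL)
    x <- x[[part]]
  }
  x
}
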