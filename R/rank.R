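# Friedman + Nemenyi ranking of competing generators across datasets,
# including the failure-rank convention for models that could not run.

#' Friedman test over a score matrix
#'
#' Non-parametric alternative to repeated-measures ANOVA: datasets are
#' blocks, models are treatments, scores are ranked within each dataset with
#' ties averaged.
#'
#' @param scores Numeric matrix, datasets (rows) x models (columns); higher
#'   scores are better.
#' @return List with `statistic` (Friedman chi-square), `p_value`, `df`.
#' @export
friedman_test <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2L) stop("need at least 2 models")
  if (nrow(scores) < 2L) stop("need at least 2 datasets")
  ft <- stats::friedman.test(scores)
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (!is.finite(stat)) {   # complete ties: no evidence of any difference
    stat <- 0
    p <- 1
  }
  list(statistic = stat, p_value = p, df = unname(ft$parameter))
}

#' Nemenyi average ranks and critical difference
#'
#' Ranks models within each dataset (rank 1 = best score, ties averaged),
#' averages ranks over datasets, and computes the Nemenyi critical difference
#' `CD = q_alpha * sqrt(k (k + 1) / (6 N))`, where `q_alpha` is the
#' studentized-range quantile divided by sqrt(2). Two models whose average
#' ranks differ by more than CD perform significantly differently at level
#' `alpha`.
#'
#' @param scores Numeric matrix, datasets x models; higher is better.
#' @param alpha Significance level in (0, 1).
#' @return A list of class `rank_table`: `average_ranks`, `rank_matrix`,
#'   `critical_difference`, `significant` (logical model x model matrix),
#'   `alpha`, `n_models`, `n_datasets`.
#' @export
nemenyi_rank <- function(scores, alpha = 0.05) {
  scores <- as.matrix(scores)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  k <- ncol(scores); N <- nrow(scores)
  if (k < 2L) stop("need at least 2 models")
  rank_matrix <- t(apply(scores, 1, function(row) rank(-row)))
  avg <- colMeans(rank_matrix)
  names(avg) <- colnames(scores)
  q <- stats::qtukey(1 - alpha, nmeans = k, df = Inf) / sqrt(2)
  cd <- q * sqrt(k * (k + 1) / (6 * N))
  sig <- abs(outer(avg, avg, "-")) > cd
  structure(list(average_ranks = avg, rank_matrix = rank_matrix,
                 critical_difference = cd, significant = sig,
                 alpha = alpha, n_models = k, n_datasets = N),
            class = "rank_table")
}

#' @export
print.rank_table <- function(x, ...) {
  cat(sprintf("rank_table: %d models over %d datasets, CD(alpha=%.2f) = %.3f\n",
              x$n_models, x$n_datasets, x$alpha, x$critical_difference))
  ord <- order(x$average_ranks)
  for (i in ord)
    cat(sprintf("  %-20s %.3f\n", names(x$average_ranks)[i],
                x$average_ranks[i]))
  invisible(x)
}

#' Aggregate rankings across metric families
#'
#' Pools per-family score matrices (e.g. statistical, machine-learning and
#' privacy families) into one overall ranking. Failed (model, dataset) cells
#' are assigned the sentinel worst rank before averaging — by default one
#' worse than the number of models, echoing the convention that a failure
#' outranks every competitor. Per-family rank tables and the pooled overall
#' table are returned.
#'
#' @param family_scores Named list of score matrices, each datasets x models
#'   with identical model columns; higher is better.
#' @param failure_mask Optional logical matrix (datasets x models) per family
#'   (a named list, or one matrix recycled) marking failed runs.
#' @param alpha Significance level for critical differences.
#' @param sentinel Worst rank assigned to failures (default `n_models + 1`).
#' @return List with `overall` (a `rank_table` over the pooled rows),
#'   `per_family`, `average_ranks` (overall), `sentinel`.
#' @export
aggregate_rankings <- function(family_scores, failure_mask = NULL,
                               alpha = 0.05, sentinel = NULL) {
  stopifnot(length(family_scores) >= 1L)
  models <- colnames(family_scores[[1L]])
  for (f in family_scores)
    if (!identical(colnames(f), models)) stop("model axes mismatch")
  k <- length(models)
  if (is.null(sentinel)) sentinel <- k + 1
  get_mask <- function(fam, dims) {
    if (is.null(failure_mask)) return(base::matrix(FALSE, dims[1], dims[2]))
    m <- if (is.list(failure_mask)) failure_mask[[fam]] else failure_mask
    if (is.null(m)) base::matrix(FALSE, dims[1], dims[2]) else m
  }
  ranked <- list()
  per_family <- list()
  for (fam in names(family_scores)) {
    sc <- as.matrix(family_scores[[fam]])
    mask <- get_mask(fam, dim(sc))
    rm_ <- t(apply(sc, 1, function(row) rank(-row)))
    rm_[mask] <- sentinel
    nt <- nemenyi_rank(sc, alpha)
    nt$rank_matrix <- rm_
    nt$average_ranks <- colMeans(rm_)
    per_family[[fam]] <- nt
    ranked[[fam]] <- rm_
  }
  pooled <- do.call(rbind, ranked)
  avg <- colMeans(pooled)
  names(avg) <- models
  q <- stats::qtukey(1 - alpha, nmeans = k, df = Inf) / sqrt(2)
  cd <- q * sqrt(k * (k + 1) / (6 * nrow(pooled)))
  overall <- structure(list(average_ranks = avg, rank_matrix = pooled,
                            critical_difference = cd,
                            significant = abs(outer(avg, avg, "-")) > cd,
                            alpha = alpha, n_models = k,
                            n_datasets = nrow(pooled)),
                       class = "rank_table")
  list(overall = overall, per_family = per_family, average_ranks = avg,
       sentinel = sentinel)
}
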