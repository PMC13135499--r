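# Data-sufficiency analysis: how many training records a generator needs
# before synthetic-data quality plateaus, located via a smoothing spline and
# a kneedle-style knee detector.

#' Training-size grid
#'
#' Builds the sample-size grid used by the sufficiency analysis: from `start`
#' (default 1000) in steps of 500 up to 5000, then in steps of 5000, capped
#' at `n_total` (which is appended when the grid does not land on it).
#'
#' @param n_total Total rows available.
#' @param start First grid size.
#' @param step_small,small_cap,step_large Grid scheme parameters.
#' @return Strictly increasing integer vector ending at `n_total` or below.
#' @export
size_grid <- function(n_total, start = 1000L, step_small = 500L,
                      small_cap = 5000L, step_large = 5000L) {
  if (start > n_total) stop("start exceeds the available rows")
  sizes <- seq(start, min(small_cap, n_total), by = step_small)
  if (n_total > small_cap)
    sizes <- c(sizes, seq(small_cap + step_large, n_total, by = step_large))
  if (utils::tail(sizes, 1L) < n_total) sizes <- c(sizes, n_total)
  unique(as.integer(sizes))
}

#' Evaluate a generator along a size grid
#'
#' For each grid size: subsample the cohort (seeded), fit the generator on
#' the subsample, generate a same-size synthetic cohort, and score it
#' (column-shapes aggregate, pair-trends, quality, and the identifiability
#' risk). Generator failures at a size are recorded, not raised.
#'
#' @param cohort The full real cohort.
#' @param config Its [study_config()].
#' @param grid Sizes from [size_grid()].
#' @param generator Function `(cohort, config, n, seed)` returning a
#'   synthetic cohort; defaults to the Gaussian-copula baseline.
#' @param seeds Integer vector of replicate seeds.
#' @return A list of class `sufficiency_curve`: `sizes`, `scores` (data.frame
#'   with size, seed, metric columns), `failures`.
#' @export
evaluate_at_sizes <- function(cohort, config, grid,
                              generator = copula_generator, seeds = 1:3) {
  rows <- list(); failures <- list()
  for (size in grid) {
    for (seed in seeds) {
      set.seed(seed + size)
      idx <- sample.int(nrow(cohort), min(size, nrow(cohort)))
      sub <- cohort[idx, , drop = FALSE]
      res <- tryCatch({
        synth <- generator(sub, config, n = nrow(sub), seed = seed)
        rep_ <- similarity_report(sub, synth, config)
        enc_r <- fit_transform(sub, config)
        enc_s <- encode_with(synth, enc_r$transform, config)
        ident <- identifiability_score(enc_r$matrix, enc_s)$score
        data.frame(size = size, seed = seed,
                   column_shapes = rep_$column_shapes,
                   pair_trends = rep_$pair_trends,
                   quality = rep_$quality_score,
                   identifiability = ident)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          list(size = size, seed = seed, message = conditionMessage(res))
      } else rows[[length(rows) + 1L]] <- res
    }
  }
  structure(list(sizes = grid,
                 scores = if (length(rows)) do.call(rbind, rows) else NULL,
                 failures = failures),
            class = "sufficiency_curve")
}

#' Gaussian-copula generator in cohort space
#'
#' Convenience wrapper used as the default generator: encodes the cohort,
#' draws a copula sample in the encoded space and inverts back to a typed
#' cohort.
#'
#' @param cohort,config Training cohort and its schema.
#' @param n Rows to generate.
#' @param seed Integer seed.
#' @return A synthetic cohort `data.frame`.
#' @export
copula_generator <- function(cohort, config, n = nrow(cohort), seed = 1L) {
  enc <- fit_transform(cohort, config)
  synth_mat <- copula_baseline_sample(enc$matrix, n, seed)
  inverse_transform(synth_mat, enc$transform, config)
}

#' Knee-point detection on a performance curve
#'
#' Fits a cubic smoothing spline (smoothness chosen by generalized
#' cross-validation) and applies the kneedle procedure: both axes are
#' normalized to `[0, 1]`, the curve is rotated by subtracting the diagonal
#' (orientation — increasing/decreasing, convex/concave — is auto-detected
#' from the smoothed series), and the knee is the x of the largest local
#' maximum of the difference curve exceeding the sensitivity threshold.
#' When no such maximum exists (e.g. a straight line), the knee is declared
#' absent (`NA`) rather than fabricated.
#'
#' @param x Sizes (>= 4 points).
#' @param y Series values.
#' @param sensitivity Kneedle sensitivity (threshold = sensitivity times the
#'   mean spacing of normalized x), default 1.
#' @param spar Optional fixed smoothing parameter overriding GCV.
#' @return The knee x (an element of `x`), or `NA` if absent.
#' @export
detect_elbow <- function(x, y, sensitivity = 1, spar = NULL) {
  if (length(x) < 4L) stop("need at least 4 points")
  o <- order(x); x <- as.numeric(x[o]); y <- as.numeric(y[o])
  ys <- if (length(unique(y)) < 2L) y else {
    fit <- tryCatch(
      if (is.null(spar)) stats::smooth.spline(x, y, cv = FALSE)
      else stats::smooth.spline(x, y, spar = spar),
      error = function(e) NULL)
    if (is.null(fit)) y else stats::predict(fit, x)$y
  }
  rngx <- diff(range(x)); rngy <- diff(range(ys))
  if (rngy == 0) return(NA_real_)
  xn <- (x - min(x)) / rngx
  yn <- (ys - min(ys)) / rngy
  increasing <- utils::tail(yn, 1L) >= yn[1L]
  # map every orientation onto the concave-increasing case
  if (!increasing) yn <- 1 - yn
  secant <- xn
  concave <- mean(yn - secant) >= 0
  diffc <- if (concave) yn - xn else xn - yn
  n <- length(diffc)
  interior <- which(diffc[-c(1L, n)] >= diffc[-c(n - 1L, n)] &
                    diffc[-c(1L, n)] >= diffc[-(1:2)]) + 1L
  if (!length(interior)) return(NA_real_)
  threshold <- sensitivity * mean(diff(xn))
  best <- interior[which.max(diffc[interior])]
  if (diffc[best] < threshold) return(NA_real_)
  x[best]
}

#' Ranking-based sufficiency threshold
#'
#' Ranks the sizes against each other via average Nemenyi ranks over the
#' score columns (metric families pooled by family means), then locates the
#' knee of the rank-versus-size series. Higher scores rank better, so the
#' rank series decreases and flattens at sufficiency.
#'
#' @param curve A `sufficiency_curve`.
#' @param metrics Score columns to use.
#' @param sensitivity Passed to [detect_elbow()].
#' @return List with `elbow` (size or `NA`), `series` (size, mean rank).
#' @export
ranking_threshold <- function(curve,
                              metrics = c("column_shapes", "pair_trends"),
                              sensitivity = 1) {
  sc <- curve$scores
  if (is.null(sc) || length(unique(sc$size)) < 2L)
    stop("need scores at >= 2 sizes")
  agg <- stats::aggregate(sc[metrics], by = list(size = sc$size), FUN = mean)
  # rank sizes within each metric (rank 1 = best score), then average
  ranks <- vapply(metrics, function(m) rank(-agg[[m]]),
                  numeric(nrow(agg)))
  series <- data.frame(size = agg$size,
                       rank = rowMeans(base::matrix(ranks, nrow(agg))))
  elbow <- if (nrow(series) >= 4L)
    detect_elbow(series$size, series$rank, sensitivity) else NA_real_
  list(elbow = elbow, series = series)
}

#' Composite-score sufficiency threshold
#'
#' Normalizes each metric into `[0, 1]` within its declared (worst, best)
#' threshold range — flipping lower-is-better metrics so higher is always
#' better — takes the mean across metrics as a composite score per size, and
#' locates the knee of the composite-versus-size curve.
#'
#' @param curve A `sufficiency_curve`.
#' @param threshold_ranges Named list `metric = c(worst, best)`; defaults
#'   cover the similarity scores (`c(0, 1)`) and identifiability flipped
#'   (`c(1, 0)`).
#' @param sensitivity Passed to [detect_elbow()].
#' @return List with `elbow`, `series` (size, composite).
#' @export
composite_threshold <- function(curve,
                                threshold_ranges = list(
                                  column_shapes = c(0, 1),
                                  pair_trends = c(0, 1),
                                  identifiability = c(1, 0)),
                                sensitivity = 1) {
  sc <- curve$scores
  if (is.null(sc) || length(unique(sc$size)) < 2L)
    stop("need scores at >= 2 sizes")
  metrics <- intersect(names(threshold_ranges), names(sc))
  agg <- stats::aggregate(sc[metrics], by = list(size = sc$size), FUN = mean)
  normed <- vapply(metrics, function(m) {
    r <- threshold_ranges[[m]]
    if (r[1] == r[2]) stop(sprintf("degenerate threshold range for '%s'", m))
    pmin(1, pmax(0, (agg[[m]] - r[1]) / (r[2] - r[1])))
  }, numeric(nrow(agg)))
  series <- data.frame(size = agg$size,
                       composite = rowMeans(base::matrix(normed, nrow(agg))))
  elbow <- if (nrow(series) >= 4L)
    detect_elbow(series$size, series$composite, sensitivity) else NA_real_
  list(elbow = elbow, series = series)
}
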