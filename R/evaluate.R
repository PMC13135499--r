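# Statistical-similarity scoring and ML-utility (TSTR / augmentation)
# evaluation of synthetic cohorts.

ks_statistic <- function(a, b) {
  # two-sample KS statistic, ties handled by evaluating both ECDFs on the
  # pooled support
  support <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(support) - stats::ecdf(b)(support)))
}

tv_distance <- function(a, b, levels) {
  pa <- base::table(factor(a, levels = levels)) / length(a)
  pb <- base::table(factor(b, levels = levels)) / length(b)
  sum(abs(pa - pb)) / 2
}

#' Column shape score
#'
#' Statistical similarity of one column between real and synthetic data:
#' `1 - KS statistic` for numeric and date columns (missing cells dropped on
#' each side, with counts reported) and `1 - total variation distance` for
#' categorical and binary columns, where missing is its own category.
#'
#' @param real_column,synth_column The two columns.
#' @param role Column role (`"continuous"`, `"date"`, `"binary"`,
#'   `"categorical"`).
#' @return List with `score` in `[0, 1]`, `n_missing_real`,
#'   `n_missing_synth`.
#' @export
column_shape_score <- function(real_column, synth_column, role) {
  if (role %in% c("continuous", "date")) {
    a <- as.numeric(real_column); b <- as.numeric(synth_column)
    miss_a <- sum(is.na(a)); miss_b <- sum(is.na(b))
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) stop("no observed values to compare")
    list(score = 1 - ks_statistic(a, b),
         n_missing_real = miss_a, n_missing_synth = miss_b)
  } else {
    a <- as.character(real_column); b <- as.character(synth_column)
    a[is.na(a)] <- "(missing)"; b[is.na(b)] <- "(missing)"
    if (!length(a) || !length(b)) stop("empty columns")
    levels <- union(a, b)
    list(score = 1 - tv_distance(a, b, levels),
         n_missing_real = sum(a == "(missing)"),
         n_missing_synth = sum(b == "(missing)"))
  }
}

#' Pairwise trend score
#'
#' How well the synthetic data preserve pairwise correlations: per feature
#' pair the score is `1 - |g - g~| / 2` on the encoded matrices (so 1 means
#' identical correlation, 0 the maximal disagreement of +1 vs -1), aggregated
#' as the mean over pairs. The signed correlation-difference matrix used for
#' heatmaps is returned alongside.
#'
#' @param real,synth Encoded numeric matrices with the same columns.
#' @param method Correlation estimator.
#' @return List with `score`, `difference` (g - g~ matrix).
#' @export
pair_trend_score <- function(real, synth, method = "pearson") {
  if (ncol(real) < 2L) stop("need at least 2 columns")
  g <- pairwise_correlations(as.matrix(real), method)
  gt <- pairwise_correlations(as.matrix(synth), method)
  diff <- g - gt
  per_pair <- 1 - abs(diff[upper.tri(diff)]) / 2
  list(score = mean(per_pair), difference = diff)
}

#' Similarity report for a synthetic cohort
#'
#' Aggregates per-column shape scores and the pairwise trend score into the
#' standard report layout: the quality score is the mean of the column-shapes
#' and pair-trends aggregates; the diagnostic score is the mean of data
#' validity (values in range / category) and data structure (names and shape
#' agree).
#'
#' @param real,synth Typed cohorts on the same schema.
#' @param config The [study_config()].
#' @return A list of class `similarity_report`.
#' @export
similarity_report <- function(real, synth, config) {
  shapes <- list()
  for (name in names(config$columns)) {
    cs <- config$columns[[name]]
    if (cs$role == "identifier" || !name %in% names(synth)) next
    shapes[[name]] <- column_shape_score(real[[name]], synth[[name]], cs$role)
  }
  shape_scores <- vapply(shapes, `[[`, numeric(1), "score")
  enc_r <- fit_transform(real, config)
  enc_s <- tryCatch(encode_with(synth, enc_r$transform, config),
                    error = function(e) NULL)
  trends <- if (!is.null(enc_s) && ncol(enc_r$matrix) >= 2)
    pair_trend_score(enc_r$matrix, enc_s) else list(score = NA_real_)
  val <- validate_table(synth, config, reference = real)
  column_shapes <- mean(shape_scores)
  pair_trends <- trends$score
  structure(list(
    per_column = shapes,
    column_shapes = column_shapes,
    pair_trends = pair_trends,
    quality_score = mean(c(column_shapes, pair_trends), na.rm = TRUE),
    validity_score = val$validity_score,
    structure_score = val$structure_score,
    diagnostic_score = mean(c(val$validity_score, val$structure_score)),
    correlation_difference = trends$difference),
    class = "similarity_report")
}

# Encode a cohort with an already fitted transform (same grids/levels), so
# real and synthetic land in one feature space.
encode_with <- function(cohort, transform, config) {
  n <- nrow(cohort)
  enc <- list()
  for (name in names(config$columns)) {
    st <- transform$columns[[name]]
    if (is.null(st) || st$role == "identifier") next
    x <- cohort[[name]]
    if (st$role %in% c("continuous", "date")) {
      raw <- if (st$role == "date")
        as.numeric(encode_dates(x, transform$reference_date)) else as.numeric(x)
      miss <- is.na(raw)
      if (identical(st$variant, "level12")) {
        enc[[name]] <- ifelse(miss, -1, raw)
      } else {
        imputed <- ifelse(miss, st$median, raw)
        enc[[paste0(name, "_q")]] <-
          quantile_transform(imputed, st$grid, transform$output)
        if (st$flag) enc[[st$flag_name]] <- as.numeric(miss)
      }
    } else {
      xi <- as.character(x)
      xi[is.na(xi)] <- PLACEHOLDER
      for (lev in st$levels)
        enc[[onehot_name(name, lev)]] <- as.numeric(xi == lev)
    }
  }
  mat <- do.call(cbind, enc)
  colnames(mat) <- names(enc)
  mat
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf(
    "similarity: column shapes %.3f, pair trends %.3f, quality %.3f, diagnostic %.3f\n",
    x$column_shapes, x$pair_trends, x$quality_score, x$diagnostic_score))
  invisible(x)
}

weighted_prf <- function(truth, pred) {
  classes <- sort(unique(truth))
  w <- as.numeric(base::table(factor(truth, levels = classes))) / length(truth)
  prec <- rec <- f1 <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(pred == cl & truth == cl)
    prec[i] <- if (sum(pred == cl)) tp / sum(pred == cl) else 0
    rec[i] <- tp / sum(truth == cl)
    f1[i] <- if (prec[i] + rec[i] > 0) 2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  list(precision = sum(w * prec), recall = sum(w * rec), f1 = sum(w * f1),
       g_mean = prod(rec)^(1 / length(rec)))
}

fit_predict_one <- function(kind, x_tr, y_tr, x_te, class_weight, seed) {
  classes <- levels(y_tr)
  set.seed(seed)
  w <- if (class_weight) {
    tab <- base::table(y_tr)
    cw <- length(y_tr) / (length(classes) * as.numeric(tab))
    names(cw) <- names(tab)
    unname(cw[as.character(y_tr)])
  } else rep(1, length(y_tr))
  pred <- switch(kind,
    linear = {
      if (length(classes) == 2L) {
        df <- data.frame(x_tr, .y = as.integer(y_tr == classes[2L]))
        fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                           family = stats::binomial(),
                                           weights = w))
        p <- stats::predict(fit, newdata = data.frame(x_te), type = "response")
        classes[1L + as.integer(p > 0.5)]
      } else {
        df <- data.frame(x_tr, .y = y_tr)
        fit <- nnet::multinom(.y ~ ., data = df, weights = w, trace = FALSE)
        as.character(stats::predict(fit, newdata = data.frame(x_te)))
      }
    },
    svm = {
      cw <- if (class_weight) {
        tab <- base::table(y_tr)
        stats::setNames(length(y_tr) / (length(classes) * as.numeric(tab)),
                        names(tab))
      } else NULL
      fit <- suppressWarnings(e1071::svm(x = x_tr, y = y_tr,
                                         kernel = "radial",
                                         class.weights = cw))
      as.character(suppressWarnings(stats::predict(fit, x_te)))
    },
    xgboost = {
      fit <- xgboost::xgboost(as.matrix(x_tr), y_tr, weights = w,
                              nrounds = 30L, nthreads = 1L, seed = seed,
                              verbosity = 0L)
      as.character(stats::predict(fit, as.matrix(x_te), type = "class"))
    })
  pred
}

#' Train-Synthetic-Test-Real evaluation
#'
#' Trains a suite of class-weighted classifiers (logistic/multinomial linear
#' model, RBF support-vector machine, gradient-boosted trees) on the
#' synthetic training table and evaluates them on held-out real data,
#' reporting frequency-weighted precision/recall/F1 and the G-mean (geometric
#' mean of per-class recalls) per classifier. For a numeric target a linear
#' model is fitted instead and RMSE/MAE reported.
#'
#' @param synth_train Synthetic training cohort (never derived from
#'   `real_test` rows).
#' @param real_test Held-out real cohort.
#' @param target_column Name of the outcome column.
#' @param config The [study_config()] (used to encode features).
#' @param task `"classification"` or `"regression"`.
#' @param class_weight Apply balanced class weights (default `TRUE`).
#' @param seed Integer seed.
#' @return A list of class `tstr_report` with one metric set per classifier.
#' @export
tstr_evaluate <- function(synth_train, real_test, target_column, config,
                          task = c("classification", "regression"),
                          class_weight = TRUE, seed = 1L) {
  task <- match.arg(task)
  feat_config <- drop_column(config, target_column)
  enc_tr <- fit_transform(synth_train[setdiff(names(synth_train), target_column)],
                          feat_config)
  x_tr <- enc_tr$matrix
  x_te <- encode_with(real_test[setdiff(names(real_test), target_column)],
                      enc_tr$transform, feat_config)
  if (task == "regression") {
    y_tr <- as.numeric(synth_train[[target_column]])
    y_te <- as.numeric(real_test[[target_column]])
    df <- data.frame(x_tr, .y = y_tr)
    fit <- stats::lm(.y ~ ., data = df)
    pred <- stats::predict(fit, newdata = data.frame(x_te))
    return(structure(list(linear = list(
      rmse = sqrt(mean((pred - y_te)^2)), mae = mean(abs(pred - y_te)))),
      class = "tstr_report"))
  }
  y_tr_chr <- as.character(synth_train[[target_column]])
  y_te <- as.character(real_test[[target_column]])
  if (length(unique(y_tr_chr)) < 2L)
    stop("training data contain a single class")
  classes <- sort(unique(c(y_tr_chr, y_te)))
  y_tr <- factor(y_tr_chr, levels = classes)
  res <- list()
  for (kind in c("linear", "svm", "xgboost")) {
    pred <- fit_predict_one(kind, x_tr, y_tr, x_te, class_weight, seed)
    res[[kind]] <- weighted_prf(y_te, pred)
  }
  structure(res, class = "tstr_report")
}

drop_column <- function(config, name) {
  cols <- config$columns[setdiff(names(config$columns), name)]
  study_config(unname(cols), reference_date = format(config$reference_date),
               k_anonymity = config$k_anonymity,
               missing_marker = config$missing_marker, seed = config$seed)
}

#' Augmentation evaluation
#'
#' Compares classifiers trained on real data alone with classifiers trained
#' on real plus synthetic data, both evaluated on the same held-out real
#' test set; reports the per-metric delta (augmented minus real-only).
#'
#' @param real_train,synth,real_test Cohorts on the same schema.
#' @inheritParams tstr_evaluate
#' @return List with `real_only`, `augmented`, `delta` (per classifier).
#' @export
augmentation_evaluate <- function(real_train, synth, real_test, target_column,
                                  config, class_weight = TRUE, seed = 1L) {
  base <- tstr_evaluate(real_train, real_test, target_column, config,
                        class_weight = class_weight, seed = seed)
  if (is.null(synth) || nrow(synth) == 0L) {
    zero <- lapply(base, function(m) lapply(m, function(v) 0))
    return(list(real_only = base, augmented = base, delta = zero))
  }
  aug <- tstr_evaluate(rbind(real_train, synth[names(real_train)]), real_test,
                       target_column, config, class_weight = class_weight,
                       seed = seed)
  delta <- Map(function(a, b) Map(`-`, a, b), aug, base)
  list(real_only = base, augmented = aug, delta = delta)
}
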