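test_that("column shape scores follow KS and TVD", {
  x <- rnorm(500)
  expect_equal(column_shape_score(x, x, "continuous")$score, 1)
  expect_equal(column_shape_score(x, x + 100, "continuous")$score, 0)

  real <- c(rep("A", 50), rep("B", 50))
  synth <- c(rep("A", 80), rep("B", 20))
  expect_equal(column_shape_score(real, synth, "categorical")$score, 0.7)

  # missing is its own category for categoricals, dropped (and counted) for
  # numerics
  rm_ <- c(real, rep(NA, 100))
  res <- column_shape_score(rm_, real, "categorical")
  # real: A .25, B .25, missing .5 vs synth: A .5, B .5 -> TVD 0.5
  expect_equal(res$score, 0.5)
  expect_identical(res$n_missing_real, 100L)
  num <- column_shape_score(c(x, NA, NA), x, "continuous")
  expect_identical(num$n_missing_real, 2L)
  expect_equal(num$score, 1)
  expect_error(column_shape_score(c(NA_real_), x, "continuous"),
               "no observed values")
})

test_that("pair trend score spans identical to maximally different", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  expect_equal(pair_trend_score(x, x)$score, 1)
  anti <- cbind(a = c(1, 2, 3, 4), b = c(8, 6, 4, 2))
  res <- pair_trend_score(x, anti)
  expect_equal(res$score, 0)
  expect_equal(res$difference, t(res$difference))
  expect_equal(unname(diag(res$difference)), c(0, 0))
  expect_error(pair_trend_score(x[, 1, drop = FALSE], x[, 1, drop = FALSE]),
               "2 columns")
})

test_that("similarity report aggregates recompute from their parts", {
  spec <- small_fixture(n = 250, seed = 21)
  co <- generate_cohort(spec)
  cfg <- fixture_config(spec)
  synth <- copula_generator(co, cfg, seed = 5)
  rep_ <- similarity_report(co, synth, cfg)
  expect_equal(rep_$column_shapes,
               mean(vapply(rep_$per_column, `[[`, numeric(1), "score")))
  expect_equal(rep_$quality_score,
               mean(c(rep_$column_shapes, rep_$pair_trends)))
  expect_equal(rep_$diagnostic_score,
               mean(c(rep_$validity_score, rep_$structure_score)))
  expect_true(all(vapply(rep_$per_column, `[[`, numeric(1), "score") >= 0))
  expect_true(all(vapply(rep_$per_column, `[[`, numeric(1), "score") <= 1))
  # a faithful copy scores 1 everywhere
  self <- similarity_report(co, co, cfg)
  expect_equal(self$quality_score, 1)
  expect_equal(self$diagnostic_score, 1)
})

make_separable <- function(n, seed, flip = 0) {
  set.seed(seed)
  y <- sample(c("neg", "pos"), n, TRUE)
  x1 <- ifelse(y == "pos", 3, -3) + rnorm(n, sd = 0.5)
  x2 <- ifelse(y == "pos", -2, 2) + rnorm(n, sd = 0.5)
  if (flip > 0) {
    idx <- sample(n, round(flip * n))
    y[idx] <- ifelse(y[idx] == "pos", "neg", "pos")
  }
  data.frame(x1 = x1, x2 = x2, label = y, stringsAsFactors = FALSE)
}

sep_config <- function() {
  study_config(list(column_spec("x1", "continuous"),
                    column_spec("x2", "continuous"),
                    column_spec("label", "binary",
                                categories = c("neg", "pos"))))
}

test_that("TSTR scores a faithful synthetic copy near-perfectly", {
  cfg <- sep_config()
  train <- make_separable(300, seed = 31)
  test <- make_separable(300, seed = 32)
  rep_ <- tstr_evaluate(train, test, "label", cfg, seed = 1)
  for (model in rep_) {
    expect_gte(model$g_mean, 0.95)
    expect_gte(model$f1, 0.9)
  }
})

test_that("label-shuffled synthetic training drops TSTR to chance", {
  cfg <- sep_config()
  train <- make_separable(1000, seed = 33)
  train$label <- sample(train$label)
  test <- make_separable(500, seed = 34)
  rep_ <- tstr_evaluate(train, test, "label", cfg, seed = 1)
  for (model in rep_) expect_lte(model$g_mean, 0.6)
})

test_that("single-class training data are rejected", {
  cfg <- sep_config()
  train <- make_separable(100, seed = 35)
  train$label <- "pos"
  test <- make_separable(50, seed = 36)
  expect_error(tstr_evaluate(train, test, "label", cfg), "single class")
})

test_that("class weighting lifts the G-mean under 9:1 imbalance", {
  cfg <- sep_config()
  overlapping <- function(n, seed, p_pos) {
    set.seed(seed)
    y <- sample(c("neg", "pos"), n, TRUE, prob = c(1 - p_pos, p_pos))
    data.frame(x1 = ifelse(y == "pos", 0.8, -0.8) + rnorm(n),
               x2 = ifelse(y == "pos", -0.8, 0.8) + rnorm(n),
               label = y, stringsAsFactors = FALSE)
  }
  deltas <- vapply(1:7, function(seed) {
    train <- overlapping(300, seed, p_pos = 0.1)
    test <- overlapping(400, seed + 100, p_pos = 0.5)
    w <- tstr_evaluate(train, test, "label", cfg, class_weight = TRUE,
                       seed = seed)$linear$g_mean
    u <- tstr_evaluate(train, test, "label", cfg, class_weight = FALSE,
                       seed = seed)$linear$g_mean
    w - u
  }, numeric(1))
  expect_gt(median(deltas), 0)
})

test_that("augmentation deltas behave for empty and corrupted synthesis", {
  cfg <- sep_config()
  real_train <- make_separable(80, seed = 41, flip = 0.2)
  test <- make_separable(300, seed = 42)
  none <- augmentation_evaluate(real_train, real_train[0, ], test, "label",
                                cfg, seed = 1)
  for (model in none$delta)
    for (metric in model) expect_identical(metric, 0)

  poison <- make_separable(400, seed = 43)
  poison$label <- ifelse(poison$label == "pos", "neg", "pos")
  bad <- augmentation_evaluate(real_train, poison, test, "label", cfg,
                               seed = 1)
  expect_lt(bad$delta$linear$g_mean, 0)
})

test_that("regression TSTR reports standard errors", {
  cfg <- study_config(list(column_spec("x1", "continuous"),
                           column_spec("y", "continuous")))
  set.seed(44)
  train <- data.frame(x1 = rnorm(200))
  train$y <- 2 * train$x1 + rnorm(200, sd = 0.1)
  test <- data.frame(x1 = rnorm(100))
  test$y <- 2 * test$x1 + rnorm(100, sd = 0.1)
  rep_ <- tstr_evaluate(train, test, "y", cfg, task = "regression")
  # features enter through the quantile encoding, so the fit is monotone-
  # approximate; it must still beat the constant predictor by a wide margin
  expect_lt(rep_$linear$rmse, sd(test$y) / 2)
  expect_lt(rep_$linear$mae, sd(test$y) / 2)
})
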