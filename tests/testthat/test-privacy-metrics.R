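planted_clusters <- function(groups = 10, per = 10, spread = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(groups * 2, sd = 50), groups, 2)
  x <- centers[rep(seq_len(groups), each = per), ] +
    matrix(rnorm(groups * per * 2, sd = spread), groups * per, 2)
  list(x = x, group = rep(seq_len(groups), each = per))
}

test_that("cluster k-anonymity recovers planted occupancy and falls back", {
  pc <- planted_clusters(10, 10, seed = 2)
  res <- cluster_k_anonymity(pc$x, granularities = 10, seed = 3)
  expect_identical(res$score, 10L)
  expect_length(res$fallbacks, 0)

  # 100 copies of one record: clustering degenerates, table = one cluster
  ident <- matrix(rep(c(1, 2), each = 100), 100, 2)
  res2 <- cluster_k_anonymity(ident, granularities = c(2, 5), seed = 1)
  expect_identical(res2$score, 100L)
  expect_gt(length(res2$fallbacks), 0)

  expect_error(cluster_k_anonymity(matrix(rnorm(4), 2, 2),
                                   granularities = 5), "fewer rows")
})

test_that("l-diversity counts distinct sensitive combinations per cluster", {
  pc <- planted_clusters(5, 12, seed = 4)
  const <- cbind(as.data.frame(pc$x), s = "same")
  expect_identical(
    l_diversity(const, c("V1", "V2"), "s", granularities = 5, seed = 1)$score,
    1L)
  three <- cbind(as.data.frame(pc$x), s = rep(c("a", "b", "c"), 20))
  expect_identical(
    l_diversity(three, c("V1", "V2"), "s", granularities = 5, seed = 1)$score,
    3L)
  uniq <- cbind(as.data.frame(pc$x), s = as.character(1:60))
  expect_identical(
    l_diversity(uniq, c("V1", "V2"), "s", granularities = 5, seed = 1)$score,
    12L)
})

test_that("k-map scores the most vulnerable real cluster", {
  pc <- planted_clusters(5, 20, seed = 6)
  self <- k_map(pc$x, pc$x, granularities = 5, seed = 2)
  own <- cluster_k_anonymity(pc$x, granularities = 5, seed = 2)
  expect_identical(self$score, own$score)

  # synthetic concentrated near one planted center leaves clusters empty
  conc <- pc$x[pc$group == 1, ][rep(1, 40), ]
  expect_identical(k_map(pc$x, conc, granularities = 5, seed = 2)$score, 0L)

  # uniform synthetic spreads roughly n/granularity per cluster
  uni <- pc$x[sample(nrow(pc$x), 100, replace = TRUE), ]
  res <- k_map(pc$x, uni, granularities = 5, seed = 2)
  expect_gt(res$score, 5)
})

test_that("delta-presence bounds sensitive overlap per cluster", {
  pc <- planted_clusters(4, 20, seed = 8)
  df <- cbind(as.data.frame(pc$x), s = rep(as.character(1:20), 4))
  copy <- delta_presence(pc$x, pc$x, c("V1", "V2"), "s",
                         granularities = 4, seed = 3,
                         real_df = df, synth_df = df)
  expect_identical(copy$score, 1)

  other <- df; other$s <- paste0("z", other$s)
  disjoint <- delta_presence(pc$x, pc$x, c("V1", "V2"), "s",
                             granularities = 4, seed = 3,
                             real_df = df, synth_df = other)
  expect_identical(disjoint$score, 0)

  # half of the real combinations replicated within each cluster
  half <- df
  half$s[half$s %in% as.character(11:20)] <- "zzz"
  planted <- delta_presence(pc$x, pc$x, c("V1", "V2"), "s",
                            granularities = 4, seed = 3,
                            real_df = df, synth_df = half)
  expect_equal(planted$score, 0.5)
})

test_that("identifiability matches its brute-force oracle", {
  set.seed(10)
  real <- matrix(rnorm(30 * 3), 30, 3)
  synth <- matrix(rnorm(25 * 3), 25, 3)
  expect_equal(identifiability_score(real, synth)$score,
               oracle_identifiability(real, synth))
  # copies of the real rows are maximally identifying
  expect_identical(identifiability_score(real, real)$score, 1)
  # far-displaced synthetic data identify nobody
  expect_identical(identifiability_score(real, synth + 1e4)$score, 0)
  # single-out uses the same construction
  expect_identical(single_out_score(real, synth)$score,
                   identifiability_score(real, synth)$score)
  expect_error(identifiability_score(real[1, , drop = FALSE], synth),
               "at least 2")
})

test_that("density MIA separates leaky from independent synthesis", {
  set.seed(12)
  train <- matrix(rnorm(500 * 2), 500, 2)
  holdout <- matrix(rnorm(500 * 2), 500, 2)
  indep <- matrix(rnorm(500 * 2), 500, 2)
  null_res <- mia_density(train, holdout, indep)
  expect_lt(abs(null_res$auc - 0.5), 0.07)

  # synthetic = noisy copies of the training rows only, far from holdout
  train_far <- matrix(rnorm(300 * 2), 300, 2)
  holdout_far <- matrix(rnorm(300 * 2), 300, 2) + 30
  leak <- train_far + matrix(rnorm(300 * 2, sd = 0.01), 300, 2)
  leak_res <- mia_density(train_far, holdout_far, leak)
  expect_gt(leak_res$auc, 0.9)

  # same records on both sides: symmetry pins the AUC at one half
  sym <- mia_density(train, train, indep)
  expect_identical(sym$auc, 0.5)
  expect_error(mia_density(train, holdout, indep, neighbors = 500),
               "neighbors")
})

test_that("CAP attribution covers deterministic, shuffled and disjoint keys", {
  keys <- expand.grid(k1 = letters[1:4], k2 = letters[1:4],
                      stringsAsFactors = FALSE)
  real <- keys[rep(1:16, 5), ]
  # sensitive is a 4-class deterministic function of the keys
  real$s <- paste0("s", (match(paste(real$k1, real$k2),
                               paste(keys$k1, keys$k2)) - 1) %% 4 + 1)
  synth <- real[sample(nrow(real)), ]
  det <- cap_score(real, synth, c("k1", "k2"), "s", "zero")
  expect_identical(det$success, 1)
  expect_identical(det$protection, 0)

  # uniformly shuffled sensitive values: modal attribution succeeds at
  # roughly chance level 1/c (averaged over shuffles to tame key-level noise)
  succ <- vapply(1:10, function(s) {
    set.seed(s)
    shuf <- synth
    shuf$s <- sample(paste0("s", 1:4), nrow(shuf), replace = TRUE)
    cap_score(real, shuf, c("k1", "k2"), "s", "zero")$success
  }, numeric(1))
  expect_lt(abs(mean(succ) - 0.25), 0.08)

  other <- synth
  other$k1 <- "zz"
  expect_identical(cap_score(real, other, c("k1", "k2"), "s", "zero")$success,
                   0)
  # generalized mode still attributes via nearest keys
  gen <- cap_score(real, synth, c("k1", "k2"), "s", "generalized")
  expect_identical(gen$success, 1)
  expect_error(cap_score(real, synth[, 1:2], c("k1", "k2"), "s"),
               "absent from synthetic")
})

test_that("inference risk reduces to CAP with the declared split", {
  keys <- data.frame(k = rep(letters[1:5], 10), stringsAsFactors = FALSE)
  real <- keys
  real$secret <- toupper(real$k)
  det <- inference_risk(real, real, "k", "secret")
  expect_identical(det$success, 1)

  set.seed(15)
  indep <- real
  indep$secret <- sample(LETTERS[1:5], nrow(indep), replace = TRUE)
  ir <- inference_risk(real, indep, "k", "secret")
  expect_lt(ir$success, 0.5)

  # empty known set: best constant guess is the modal class
  skew <- real
  skew$secret <- c(rep("A", 40), rep("B", 10))
  none <- inference_risk(skew, skew, character(0), "secret")
  expect_equal(none$success, 0.8)
})

test_that("linkability links copies but not independent synthesis", {
  set.seed(16)
  real <- matrix(rnorm(100 * 4), 100, 4)
  colnames(real) <- paste0("f", 1:4)
  split <- list(c("f1", "f2"), c("f3", "f4"))
  expect_gt(linkability_score(real, real, split)$score, 0.95)
  indep <- matrix(rnorm(100 * 4), 100, 4)
  colnames(indep) <- paste0("f", 1:4)
  expect_lt(linkability_score(real, indep, split)$score, 0.1)
  expect_error(linkability_score(real, indep,
                                 list(c("f1", "f2"), c("f2", "f3"))),
               "disjoint")
  expect_error(linkability_score(real[1, , drop = FALSE], indep, split),
               "at least 2")
})

test_that("match rate agrees with the exhaustive pair scan", {
  real <- data.frame(age = c(50, 60, 70, 80), sex = c("f", "m", "f", "m"),
                     stringsAsFactors = FALSE)
  synth <- data.frame(age = c(51, 59, 40, 80), sex = c("f", "m", "f", "f"),
                      stringsAsFactors = FALSE)
  mc <- match_config(c(age = 2, sex = 0), label = "demo")
  expect_equal(match_rate(real, synth, mc)$rate,
               oracle_match_rate(real, synth, c(age = 2, sex = 0)))
  expect_equal(match_rate(real, synth, mc)$rate, 0.5)
  expect_identical(match_rate(real, real, mc)$rate, 1)
  far <- synth; far$age <- far$age + 1000
  expect_identical(match_rate(real, far, mc)$rate, 0)
  expect_error(match_rate(real, synth, match_config(c(ghost = 1))),
               "absent column")
})

test_that("the real-to-real baseline excludes self matches", {
  mc <- match_config(c(age = 0, sex = 0))
  same <- data.frame(id = as.character(1:6), age = 50, sex = "f",
                     stringsAsFactors = FALSE)
  expect_identical(baseline_match_rate(same, mc)$rate, 1)
  uniq <- data.frame(id = as.character(1:6), age = seq(10, 60, 10),
                     sex = rep(c("f", "m"), 3), stringsAsFactors = FALSE)
  expect_identical(baseline_match_rate(uniq, mc)$rate, 0)
  # planted twins: half the rows have exactly one cross-individual twin
  twins <- data.frame(id = as.character(1:8),
                      age = c(50, 50, 60, 60, 1, 2, 3, 4),
                      sex = "f", stringsAsFactors = FALSE)
  expect_equal(baseline_match_rate(twins, mc)$rate, 0.5)
  expect_error(baseline_match_rate(uniq, mc, id_column = "pid"),
               "id column")
})

test_that("metrics are invariant to row order and carry orientations", {
  set.seed(18)
  real <- matrix(rnorm(40 * 3), 40, 3)
  synth <- matrix(rnorm(40 * 3), 40, 3)
  perm_r <- real[sample(nrow(real)), ]
  perm_s <- synth[sample(nrow(synth)), ]
  expect_equal(identifiability_score(real, synth)$score,
               identifiability_score(perm_r, perm_s)$score)
  rep_ <- privacy_report(real, synth, seed = 4)
  for (entry in rep_)
    expect_true(entry$orientation %in% c("higher_safer", "lower_safer"))
})

test_that("planted leaky synthesis scores worse than safe synthesis", {
  set.seed(19)
  real <- matrix(rnorm(200 * 3), 200, 3)
  leaky <- real + matrix(rnorm(200 * 3, sd = 0.01), 200, 3)
  safe <- matrix(rnorm(200 * 3), 200, 3)
  expect_gt(identifiability_score(real, leaky)$score,
            identifiability_score(real, safe)$score)
  colnames(real) <- colnames(leaky) <- colnames(safe) <- paste0("f", 1:3)
  split <- list(c("f1", "f2"), "f3")
  expect_gt(linkability_score(real, leaky, split)$score,
            linkability_score(real, safe, split)$score)
})
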