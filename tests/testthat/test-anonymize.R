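test_that("greedy_filter finds the globally rarest value deterministically", {
  tab <- data.frame(sex = c(rep("F", 3), rep("M", 7)),
                    smoker = c(rep("Y", 5), rep("N", 5)),
                    stringsAsFactors = FALSE)
  f <- greedy_filter(tab)
  expect_identical(f$column, "sex")
  expect_identical(f$value, "F")
  expect_identical(f$count, 3L)

  one <- data.frame(g = rep("x", 12), stringsAsFactors = FALSE)
  f1 <- greedy_filter(one)
  expect_identical(f1$value, "x")
  expect_identical(f1$count, 12L)

  none <- data.frame(row.names = 1:9)
  f0 <- greedy_filter(none)
  expect_true(is.na(f0$column))
  expect_identical(f0$count, 9L)

  # ties break by column order then label order
  tie <- data.frame(b = c("x", "y"), a = c("p", "q"),
                    stringsAsFactors = FALSE)
  ft <- greedy_filter(tie)
  expect_identical(ft$column, "b")
  expect_identical(ft$value, "x")
})

test_that("greedy and brute-force privacy tests agree on the basics", {
  same <- data.frame(g = rep("x", 10), h = rep("y", 10),
                     stringsAsFactors = FALSE)
  expect_true(greedy_privacy_test(same, 10))
  expect_true(brute_force_privacy_test(same, 10))

  rare <- data.frame(g = c(rep("a", 4), rep("b", 8)), stringsAsFactors = FALSE)
  expect_false(greedy_privacy_test(rare, 5))
  expect_false(brute_force_privacy_test(rare, 5))

  expect_false(brute_force_privacy_test(
    data.frame(g = "a", stringsAsFactors = FALSE), 2))

  # marginals fine but a joint cell is small
  joint <- data.frame(a = c(rep("x", 6), rep("y", 6)),
                      b = c(rep("p", 5), "q", rep("q", 5), "p"),
                      stringsAsFactors = FALSE)
  expect_false(brute_force_privacy_test(joint, 2))
})

test_that("greedy false implies brute-force false on random tables", {
  for (seed in 1:40) {
    tab <- random_cat_table(seed, max_cols = 4L, max_rows = 60L)
    k <- sample(c(2L, 5L), 1)
    if (!greedy_privacy_test(tab, k))
      expect_false(brute_force_privacy_test(tab, k))
  }
})

test_that("privacy_satisfied equals brute-force truth and short-circuits", {
  for (seed in 41:70) {
    tab <- random_cat_table(seed, max_cols = 3L, max_rows = 50L)
    k <- sample(c(2L, 5L), 1)
    expect_identical(privacy_satisfied(tab, k),
                     brute_force_privacy_test(tab, k))
  }
  rare <- data.frame(g = c(rep("a", 2), rep("b", 50)), stringsAsFactors = FALSE)
  ins <- privacy_satisfied(rare, 5, instrument = TRUE)
  expect_false(ins$ok)
  expect_false(ins$brute_force_ran)
  empty_cols <- data.frame(row.names = 1:5)
  expect_true(privacy_satisfied(empty_cols, 2))
})

test_that("the brute-force state budget fails loudly, never silently", {
  # six constant columns: every filter chain keeps all rows, so the
  # recursion must visit all 2^6 column subsets
  wide <- as.data.frame(lapply(1:6, function(j) rep("x", 50)),
                        col.names = paste0("c", 1:6))
  expect_error(brute_force_privacy_test(wide, 2, max_states = 10),
               "state budget")
  expect_true(brute_force_privacy_test(wide, 2, max_states = 1000))
})

test_that("built-in hierarchies encode the clinical bin edges", {
  h <- builtin_hierarchies()
  bmi1 <- h$bmi$levels[[1]]
  expect_identical(apply_binner_level(c(18.4, 18.5, 24.99, 25, 30), bmi1),
                   c("underweight", "normal", "normal", "overweight",
                     "obesity"))
  bmi2 <- h$bmi$levels[[2]]
  expect_identical(apply_binner_level(c(24.99, 25, 30), bmi2),
                   c("normal-", "overweight+", "overweight+"))
  by1 <- h$birth_year$levels[[1]]
  expect_identical(apply_binner_level(c(1939, 1949, 1955, 1961), by1),
                   c("<1940", "1940s", "1950s", "1960+"))
  by2 <- h$birth_year$levels[[2]]
  expect_identical(apply_binner_level(c(1949, 1950), by2),
                   c("<1950", "1950+"))
  expect_identical(apply_binner_level(c(20, NA), bmi1)[2], "missing")
})

test_that("coarsening conserves rows between levels", {
  h <- builtin_hierarchies()$bmi
  set.seed(5)
  v <- runif(500, 15, 42)
  l1 <- table(apply_binner_level(v, h$levels[[1]]))
  l2 <- table(apply_binner_level(v, h$levels[[2]]))
  expect_identical(unname(l2["normal-"]),
                   unname(l1["underweight"] + l1["normal"]))
  expect_identical(unname(l2["overweight+"]),
                   unname(l1["overweight"] + l1["obesity"]))
})

test_that("adaptive binning reaches verified total k-anonymity", {
  set.seed(13)
  coh <- data.frame(
    birth_year = sample(1925:1975, 500, TRUE),
    bmi = runif(500, 16, 40),
    sex = sample(c("female", "male"), 500, TRUE),
    smoking_status = sample(c("Never", "Former", "Current"), 500, TRUE),
    stringsAsFactors = FALSE)
  ab <- adaptive_bin(coh, 10, builtin_hierarchies(),
                     columns = c("birth_year", "bmi", "sex",
                                 "smoking_status"))
  expect_true(brute_force_privacy_test(ab$table, 10))

  # duplicated rows are already private at the finest level
  dup <- coh[rep(1, 30), ]
  ab2 <- adaptive_bin(dup, 2, builtin_hierarchies(),
                      columns = c("birth_year", "bmi", "sex"))
  expect_identical(unname(ab2$levels), rep(1L, 3))
  expect_identical(ab2$iterations, 0L)

  # a unique full-resolution row forces at least one coarsening or removal
  adv <- coh[1:40, ]
  adv$bmi[1] <- 99
  ab3 <- adaptive_bin(adv, 2, builtin_hierarchies(),
                      columns = c("birth_year", "bmi", "sex"))
  expect_true(ab3$iterations >= 1L)
  expect_true(brute_force_privacy_test(ab3$table, 2))
})

test_that("aggregate counts on a verified view are never below k", {
  set.seed(17)
  coh <- data.frame(birth_year = sample(1930:1970, 400, TRUE),
                    bmi = runif(400, 17, 38),
                    sex = sample(c("female", "male"), 400, TRUE),
                    stringsAsFactors = FALSE)
  ab <- adaptive_bin(coh, 10, builtin_hierarchies(),
                     columns = c("birth_year", "bmi", "sex"))
  expect_identical(aggregate_counts(ab), nrow(coh))
  for (cn in names(ab$table)) {
    for (v in unique(ab$table[[cn]])) {
      n <- aggregate_counts(ab, stats::setNames(list(v), cn))
      expect_true(n == 0L || n >= 10L)
    }
  }
  # full conjunctions over all retained columns
  combos <- unique(ab$table)
  for (i in seq_len(min(nrow(combos), 20))) {
    n <- aggregate_counts(ab, as.list(combos[i, , drop = FALSE]))
    expect_true(n == 0L || n >= 10L)
  }
  expect_error(aggregate_counts(ab, list(ghost = "x")), "removed or unknown")
})

test_that("adaptive binning is deterministic", {
  set.seed(23)
  coh <- data.frame(birth_year = sample(1930:1970, 200, TRUE),
                    bmi = runif(200, 17, 38),
                    stringsAsFactors = FALSE)
  a <- adaptive_bin(coh, 10, builtin_hierarchies())
  b <- adaptive_bin(coh, 10, builtin_hierarchies())
  expect_identical(a$table, b$table)
  expect_identical(a$levels, b$levels)
})
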