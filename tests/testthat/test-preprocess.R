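test_that("dates encode as day counts from the reference point", {
  expect_identical(encode_dates(as.Date("2010-05-20"), "2000-01-01"), 3792L)
  expect_identical(encode_dates(as.Date("2003-02-01"), "2000-01-01"), 1127L)
  expect_identical(encode_dates(as.Date("2000-01-01"), "2000-01-01"), 0L)
  expect_identical(encode_dates(as.Date(c("1999-12-31", NA)), "2000-01-01"),
                   c(-1L, NA))
  expect_error(encode_dates(c("2010-13-40"), "2000-01-01"), "malformed")
})

test_that("the worked example encodes with the expected flags and one-hots", {
  enc <- fit_transform(worked_example(), worked_example_config())
  m <- enc$matrix
  expect_identical(unname(m[, "diagnosis_date_q_m"]), c(0, 1, 0, 0, 1))
  expect_identical(unname(m[, "blood_pressure_q_m"]), c(0, 1, 0, 0, 0))
  # record 3: placeholder level active, all declared levels 0
  expect_identical(unname(m[3, c("smoking_status=Current",
                                 "smoking_status=Former",
                                 "smoking_status=Never",
                                 "smoking_status=Unknown")]),
                   c(0, 0, 0, 1))
  # records 1, 2, 5 share the diagnosis quantile (median imputation lands on
  # record 1's date)
  dq <- m[, "diagnosis_date_q"]
  expect_identical(dq[1], dq[2])
  expect_identical(dq[1], dq[5])
  expect_true(dq[4] < dq[1] && dq[1] < dq[3])
  # blood pressure ordering 95 < 120 < 130(imputed) < 140 < 180
  bp <- m[, "blood_pressure_q"]
  expect_identical(order(bp), c(4L, 1L, 2L, 5L, 3L))
})

test_that("quantile transform is monotone, tie-stable and grid-bijective", {
  set.seed(8)
  for (rep_ in 1:10) {
    x <- round(rnorm(40, 50, 20), 1)
    grid <- tabsafe:::fit_quantile_grid(x)
    # minimum maps to the lowest grid level, never below
    expect_equal(quantile_transform(min(x), grid), min(grid$levels))
    # monotone non-decreasing
    probe <- sort(runif(50, min(x) - 10, max(x) + 10))
    out <- quantile_transform(probe, grid)
    expect_true(all(diff(out) >= -1e-12))
    # ties map equal
    expect_identical(quantile_transform(c(x[1], x[1]), grid)[1],
                     quantile_transform(c(x[1], x[1]), grid)[2])
    # bijective on the grid
    expect_equal(quantile_inverse(quantile_transform(grid$values, grid), grid),
                 grid$values, tolerance = 1e-12)
    # out-of-range clamps
    expect_equal(quantile_transform(max(x) + 100, grid), max(grid$levels))
  }
  expect_error(quantile_transform(1, list(values = numeric(0),
                                          levels = numeric(0))), "empty")
})

test_that("gaussian output law is the normal quantile of the uniform level", {
  x <- c(1, 2, 3, 4, 5)
  grid <- tabsafe:::fit_quantile_grid(x)
  expect_equal(quantile_transform(x, grid, output = "gaussian"),
               qnorm(quantile_transform(x, grid)))
  expect_equal(quantile_inverse(
    quantile_transform(x, grid, "gaussian"), grid, "gaussian"), x)
})

test_that("the round trip restores the worked example exactly", {
  co <- worked_example()
  cfg <- worked_example_config()
  enc <- fit_transform(co, cfg)
  expect_identical(inverse_transform(enc, config = cfg), co)

  # all-flags-zero synthetic row has no missing cells
  m <- enc$matrix
  m[, grep("_q_m$", colnames(m))] <- 0
  m[3, "smoking_status=Unknown"] <- 0
  m[3, "smoking_status=Never"] <- 1
  inv <- inverse_transform(m, enc$transform, cfg)
  expect_false(anyNA(inv))

  # argmax at placeholder restores missing
  m2 <- enc$matrix
  m2[1, "smoking_status=Former"] <- 0
  m2[1, "smoking_status=Unknown"] <- 0.9
  inv2 <- inverse_transform(m2, enc$transform, cfg)
  expect_true(is.na(inv2$smoking_status[1]))
})

test_that("round trip is the identity on randomized fixture cohorts", {
  for (seed in 1:20) {
    spec <- small_fixture(n = 40, seed = seed)
    co <- generate_cohort(spec)
    cfg <- fixture_config(spec)
    enc <- fit_transform(co, cfg)
    inv <- inverse_transform(enc, config = cfg)
    expect_identical(inv$sampling_date, co$sampling_date)
    expect_identical(inv$smoking_status, co$smoking_status)
    expect_identical(inv$sex, co$sex)
    expect_identical(inv$cancer, co$cancer)
    expect_equal(inv$height, co$height, tolerance = 1e-9)
    expect_equal(inv$weight, co$weight, tolerance = 1e-9)
    # flags equal the missingness mask exactly
    expect_identical(unname(enc$matrix[, "weight_q_m"]),
                     as.numeric(is.na(co$weight)))
  }
})

test_that("encoded layout follows the dimensional accounting", {
  spec <- small_fixture(n = 60, seed = 9)
  co <- generate_cohort(spec)
  cfg <- fixture_config(spec)
  enc <- fit_transform(co, cfg)
  expect_identical(ncol(enc$matrix), encoded_width(enc))
  # continuous: height, weight, bmi + sampling_date, each with a flag
  # categorical: sex (2+1), smoking (3+1), cancer (2+1)
  expect_identical(ncol(enc$matrix), as.integer(4 * 2 + 3 + 4 + 3))
  # one-hot partition: exactly one active level per row and source
  for (src in c("sex", "smoking_status", "cancer")) {
    block <- enc$matrix[, startsWith(colnames(enc$matrix), paste0(src, "=")),
                        drop = FALSE]
    expect_true(all(rowSums(block) == 1))
  }
  expect_identical(unname(enc$provenance$kind[enc$provenance$encoded == "height_q"]),
                   "quantile_value")
})

test_that("indicator threshold limits flags to high-missingness columns", {
  spec <- small_fixture(n = 120, seed = 4)   # weight 30%, date 50% missing
  co <- generate_cohort(spec)
  cfg <- fixture_config(spec)
  enc <- fit_transform(co, cfg, indicator_threshold = 0.4)
  expect_false("weight_q_m" %in% colnames(enc$matrix))
  expect_true("sampling_date_q_m" %in% colnames(enc$matrix))
})

test_that("the level-1/2 variant imputes with -1 and inverts collision-free", {
  cfg <- study_config(list(column_spec("v", "continuous"),
                           column_spec("g", "categorical",
                                       categories = c("a", "b"))))
  co <- data.frame(v = c(5, NA, 7), g = c("a", NA, "b"),
                   stringsAsFactors = FALSE)
  enc <- fit_transform_level12(co, cfg)
  expect_identical(unname(enc$matrix[, "v"]), c(5, -1, 7))
  inv <- inverse_transform(enc, config = cfg)
  expect_identical(inv, co)

  # no missing: passthrough equals input
  co2 <- data.frame(v = c(1, 2, 3), g = c("a", "b", "a"),
                    stringsAsFactors = FALSE)
  enc2 <- fit_transform_level12(co2, cfg)
  expect_identical(unname(enc2$matrix[, "v"]), co2$v)

  # -1 observed in the data: inversion must not fabricate missingness
  co3 <- data.frame(v = c(-1, NA, 3), g = c("a", "a", "b"),
                    stringsAsFactors = FALSE)
  enc3 <- fit_transform_level12(co3, cfg)
  inv3 <- inverse_transform(enc3, config = cfg)
  expect_identical(inv3$v, c(-1, -1, 3))
})

test_that("degenerate inputs are rejected with clear errors", {
  cfg <- study_config(list(column_spec("v", "continuous")))
  expect_error(fit_transform(data.frame(v = c(NA_real_, NA_real_)), cfg),
               "no observed values")
})
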