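#' Specify a synthetic biobank-like cohort
#'
#' Describes the data-generating process for a test cohort emulating the
#' variable families of a population biobank: demographics, anthropometric and
#' blood measurements, calendar dates, smoking status, sex, and disease
#' indicators with sex-specific admissibility. The continuous block is drawn
#' from a Gaussian copula with declared marginals so pairwise correlations can
#' be planted exactly; a deterministic BMI column (weight / height^2) plants a
#' nonlinear dependency; per-column missingness is injected MCAR or MAR
#' afterwards.
#'
#' @param n_rows Number of records.
#' @param continuous Named list; each element
#'   `list(mean=, sd=, dist=c("normal","lognormal"))` describes one marginal
#'   (lognormal parameters are on the log scale, for skewed lab values).
#' @param correlation Target correlation matrix for the continuous block
#'   (symmetric, unit diagonal, positive semi-definite), in the order of
#'   `names(continuous)`.
#' @param dates Named list; each element `list(from=, to=)` gives an ISO date
#'   range sampled uniformly.
#' @param categorical Named list; each element a named numeric vector of
#'   category probabilities.
#' @param sex_levels Two labels; the first is treated as female.
#' @param sex_prob Probability of the first sex level.
#' @param diseases Named list; each element
#'   `list(rate=, sex=c("any","female","male"))` — a binary disease column with
#'   the given prevalence, restricted to the admissible sex.
#' @param derive_bmi If `TRUE` and `height`/`weight` are present, adds
#'   `bmi = weight / (height/100)^2` (height in cm).
#' @param missingness Named list; each element
#'   `list(rate=, mechanism=c("MCAR","MAR"), condition=, rates=)` — see
#'   [inject_missingness()]. Rates must lie in the 0.004-0.90 envelope seen in
#'   real high-missingness registries, up to 0.95.
#' @param seed Integer seed; same spec + seed gives a bitwise-identical cohort.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_rows = 1000L,
                         continuous = list(
                           height = list(mean = 170, sd = 10, dist = "normal"),
                           weight = list(mean = 78, sd = 14, dist = "normal"),
                           waist = list(mean = 94, sd = 12, dist = "normal"),
                           cholesterol = list(mean = 1.7, sd = 0.2, dist = "lognormal")),
                         correlation = NULL,
                         dates = list(sampling_date = list(from = "1995-01-01",
                                                           to = "2010-12-31")),
                         categorical = list(
                           smoking_status = c(Never = 0.5, Former = 0.3, Current = 0.2)),
                         sex_levels = c("female", "male"),
                         sex_prob = 0.5,
                         diseases = list(cancer = list(rate = 0.15, sex = "any")),
                         derive_bmi = TRUE,
                         missingness = list(),
                         seed = 1L) {
  p <- length(continuous)
  if (is.null(correlation)) {
    correlation <- diag(p)
    if (p >= 2) correlation[correlation == 0] <- 0.3
    diag(correlation) <- 1
  }
  correlation <- as.matrix(correlation)
  if (!isSymmetric(unname(correlation)) || any(abs(diag(correlation) - 1) > 1e-12))
    stop("correlation must be symmetric with unit diagonal")
  if (min(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("correlation matrix is not positive semi-definite")
  for (m in missingness) {
    r <- max(c(m$rate, m$rates))
    if (r >= 0.95) stop("missingness rate must be below 0.95")
  }
  structure(list(n_rows = as.integer(n_rows), continuous = continuous,
                 correlation = correlation, dates = dates,
                 categorical = categorical, sex_levels = sex_levels,
                 sex_prob = sex_prob, diseases = diseases,
                 derive_bmi = isTRUE(derive_bmi), missingness = missingness,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic cohort from a fixture specification
#'
#' @param spec A [fixture_spec()].
#' @return A typed cohort `data.frame` with an `id` identifier column.
#' @seealso [fixture_config()] for the matching [study_config()].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_rows
  set.seed(spec$seed)
  out <- list(id = as.character(seq_len(n)))

  p <- length(spec$continuous)
  if (p > 0) {
    L <- chol_psd(spec$correlation)
    z <- matrix(stats::rnorm(n * p), n, p) %*% L
    u <- stats::pnorm(z)
    for (j in seq_len(p)) {
      m <- spec$continuous[[j]]
      out[[names(spec$continuous)[j]]] <-
        if ((m$dist %||% "normal") == "lognormal")
          stats::qlnorm(u[, j], meanlog = m$mean, sdlog = m$sd)
        else stats::qnorm(u[, j], mean = m$mean, sd = m$sd)
    }
  }
  if (spec$derive_bmi && all(c("height", "weight") %in% names(out)))
    out$bmi <- out$weight / (out$height / 100)^2

  for (dn in names(spec$dates)) {
    d <- spec$dates[[dn]]
    from <- as.Date(d$from); to <- as.Date(d$to)
    out[[dn]] <- from + floor(stats::runif(n) * (as.integer(to - from) + 1L))
  }
  out$sex <- ifelse(stats::runif(n) < spec$sex_prob,
                    spec$sex_levels[1L], spec$sex_levels[2L])
  for (cn in names(spec$categorical)) {
    pr <- spec$categorical[[cn]]
    out[[cn]] <- sample(names(pr), n, replace = TRUE, prob = pr)
  }
  for (dn in names(spec$diseases)) {
    d <- spec$diseases[[dn]]
    admissible <- switch(d$sex %||% "any",
      any = rep(TRUE, n),
      female = out$sex == spec$sex_levels[1L],
      male = out$sex == spec$sex_levels[2L])
    out[[dn]] <- ifelse(admissible & stats::runif(n) < d$rate, "yes", "no")
  }
  cohort <- as.data.frame(out, stringsAsFactors = FALSE)

  for (cn in names(spec$missingness)) {
    m <- spec$missingness[[cn]]
    cohort <- inject_missingness(cohort, cn,
                                 mechanism = m$mechanism %||% "MCAR",
                                 rate = m$rate %||% 0,
                                 condition = m$condition,
                                 rates = m$rates,
                                 seed = spec$seed + match(cn, names(spec$missingness)))
  }
  cohort
}

chol_psd <- function(R, ridge = 1e-10) {
  for (i in 0:20) {
    res <- tryCatch(chol(R + diag(ridge * 10^i - ridge * (i == 0), nrow(R))),
                    error = function(e) NULL)
    if (!is.null(res)) return(res)
  }
  stop("correlation matrix could not be factorized")
}

#' Study configuration matching the default fixture cohort
#'
#' @param spec The [fixture_spec()] the cohort came from.
#' @param k_anonymity,seed Passed to [study_config()].
#' @return A [study_config()] describing [generate_cohort()] output.
#' @export
fixture_config <- function(spec = fixture_spec(), k_anonymity = 10L,
                           seed = spec$seed) {
  cols <- list(column_spec("id", "identifier"))
  for (cn in names(spec$continuous))
    cols <- c(cols, list(column_spec(cn, "continuous")))
  if (spec$derive_bmi && all(c("height", "weight") %in% names(spec$continuous)))
    cols <- c(cols, list(column_spec("bmi", "continuous", binner = "bmi")))
  for (dn in names(spec$dates))
    cols <- c(cols, list(column_spec(dn, "date")))
  cols <- c(cols, list(column_spec("sex", "binary", categories = spec$sex_levels)))
  for (cn in names(spec$categorical))
    cols <- c(cols, list(column_spec(cn, "categorical",
                                     categories = names(spec$categorical[[cn]]))))
  for (dn in names(spec$diseases))
    cols <- c(cols, list(column_spec(dn, "binary", categories = c("no", "yes"),
                                     sensitive = TRUE)))
  study_config(cols, k_anonymity = k_anonymity, seed = seed)
}

#' Inject missingness into one cohort column
#'
#' MCAR blanks cells independently with the given rate; MAR makes the
#' missingness probability depend on a conditioning column through per-stratum
#' rates (a logistic mechanism degenerated to one rate per stratum).
#'
#' @param cohort A cohort `data.frame`.
#' @param column Column to modify.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param rate MCAR missingness probability in `[0, 1)`.
#' @param condition For MAR: name of the conditioning column.
#' @param rates For MAR: named vector of per-stratum missingness rates, keyed
#'   by the conditioning column's values.
#' @param seed Integer seed.
#' @return The cohort with `NA`s injected into `column` only.
#' @export
inject_missingness <- function(cohort, column, mechanism = c("MCAR", "MAR"),
                               rate = 0, condition = NULL, rates = NULL,
                               seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (!column %in% names(cohort)) stop(sprintf("no column '%s'", column))
  n <- nrow(cohort)
  set.seed(seed)
  if (mechanism == "MCAR") {
    if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
    drop <- stats::runif(n) < rate
  } else {
    if (is.null(condition) || !condition %in% names(cohort))
      stop("MAR requires a declared conditioning column present in the cohort")
    if (is.null(rates)) stop("MAR requires per-stratum 'rates'")
    strata <- as.character(cohort[[condition]])
    p <- unname(rates[strata])
    p[is.na(p)] <- 0
    drop <- stats::runif(n) < p
  }
  cohort[[column]][drop] <- NA
  cohort
}

#' The five-record fictive worked example
#'
#' A tiny fixed cohort used throughout the documentation and tests: five
#' patients with a diagnosis date, a blood pressure, and a smoking status,
#' four cells missing (records 2 and 5 lack the diagnosis date, record 2 the
#' blood pressure, record 3 the smoking status).
#'
#' @return A typed cohort `data.frame` with columns `id`, `diagnosis_date`,
#'   `blood_pressure`, `smoking_status`.
#' @export
worked_example <- function() {
  data.frame(
    id = as.character(1:5),
    diagnosis_date = as.Date(c("2010-05-20", NA, "2015-07-13", "2003-02-01", NA)),
    blood_pressure = c(120, NA, 180, 95, 140),
    smoking_status = c("Former", "Current", NA, "Never", "Current"),
    stringsAsFactors = FALSE)
}

#' @rdname worked_example
#' @return `worked_example_config()`: the matching [study_config()] with
#'   reference date 2000-01-01.
#' @export
worked_example_config <- function() {
  study_config(list(
    column_spec("id", "identifier"),
    column_spec("diagnosis_date", "date"),
    column_spec("blood_pressure", "continuous", units = "mmHg"),
    column_spec("smoking_status", "categorical",
                categories = c("Current", "Former", "Never"))),
    reference_date = "2000-01-01")
}
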