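# Shared fixtures built in code: small cohorts, random categorical tables,
# and brute-force oracles used across test files.

small_fixture <- function(n = 200, seed = 1, miss = TRUE) {
  fixture_spec(
    n_rows = n,
    continuous = list(height = list(mean = 170, sd = 10, dist = "normal"),
                      weight = list(mean = 78, sd = 14, dist = "normal")),
    correlation = matrix(c(1, 0.5, 0.5, 1), 2),
    dates = list(sampling_date = list(from = "2000-01-01", to = "2009-12-31")),
    categorical = list(smoking_status = c(Never = 0.5, Former = 0.3,
                                          Current = 0.2)),
    diseases = list(cancer = list(rate = 0.2, sex = "any")),
    missingness = if (miss)
      list(weight = list(rate = 0.3),
           sampling_date = list(rate = 0.5)) else list(),
    seed = seed)
}

# random small categorical table for anonymization tests
random_cat_table <- function(seed, max_cols = 6L, max_rows = 400L) {
  set.seed(seed)
  ncol_ <- sample(2:max_cols, 1)
  nrow_ <- sample(20:max_rows, 1)
  as.data.frame(lapply(seq_len(ncol_), function(j)
    sample(letters[seq_len(sample(2:4, 1))], nrow_, replace = TRUE)),
    col.names = paste0("c", seq_len(ncol_)), stringsAsFactors = FALSE)
}

# hierarchy that halves the raw-value groups at each coarser level, ending in
# one all-encompassing bin, so adaptive binning can terminate without removal
collapse_hierarchy <- function(attribute, values) {
  groups <- stats::setNames(as.list(values), values)
  lvls <- list(list(type = "group", groups = groups))
  while (length(groups) > 1L) {
    merged <- list()
    idx <- seq_along(groups)
    for (i in seq_len(ceiling(length(groups) / 2))) {
      take <- idx[(2 * i - 1):min(2 * i, length(groups))]
      merged[[paste(names(groups)[take], collapse = "+")]] <-
        unname(unlist(groups[take]))
    }
    lvls[[length(lvls) + 1L]] <- list(type = "group", groups = merged)
    groups <- merged
  }
  binner_hierarchy(attribute, lvls)
}

# O(n^2) oracle for the closer-than-second-real-neighbour score
oracle_identifiability <- function(real, synth) {
  real <- as.matrix(real); synth <- as.matrix(synth)
  mu <- colMeans(real); sdv <- apply(real, 2, sd); sdv[sdv == 0] <- 1
  rs <- sweep(sweep(real, 2, mu), 2, sdv, "/")
  ss <- sweep(sweep(synth, 2, mu), 2, sdv, "/")
  hits <- 0L
  for (i in seq_len(nrow(rs))) {
    d_syn <- min(sqrt(colSums((t(ss) - rs[i, ])^2)))
    d_real <- sort(sqrt(colSums((t(rs[-i, , drop = FALSE]) - rs[i, ])^2)))
    if (d_syn < d_real[2]) hits <- hits + 1L
  }
  hits / nrow(rs)
}

# O(n^2) oracle for the match rate
oracle_match_rate <- function(real, synth, spans) {
  cols <- names(spans)
  hit <- logical(nrow(synth))
  for (i in seq_len(nrow(synth))) {
    for (j in seq_len(nrow(real))) {
      ok <- TRUE
      for (cn in cols) {
        a <- synth[[cn]][i]; b <- real[[cn]][j]
        ok <- ok && if (is.na(a) || is.na(b)) is.na(a) && is.na(b)
        else if (is.numeric(real[[cn]]) || inherits(real[[cn]], "Date"))
          abs(as.numeric(a) - as.numeric(b)) <= spans[[cn]]
        else as.character(a) == as.character(b)
        if (!ok) break
      }
      if (ok) { hit[i] <- TRUE; break }
    }
  }
  mean(hit)
}

# from-scratch Friedman statistic (average-tie ranks, no tie correction)
oracle_friedman <- function(scores) {
  N <- nrow(scores); k <- ncol(scores)
  r <- t(apply(scores, 1, rank))
  Rj <- colSums(r)
  12 / (N * k * (k + 1)) * sum(Rj^2) - 3 * N * (k + 1)
}
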