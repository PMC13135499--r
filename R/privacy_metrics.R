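# Disclosure-risk metric suite. All metrics operate on numeric-encoded
# matrices (distance-based metrics standardize with real-fitted parameters)
# or on raw cohort data.frames (attribution/match metrics). Every score
# carries an orientation: "higher_safer" or "lower_safer".

standardize_pair <- function(real, synth) {
  real <- as.matrix(real); synth <- as.matrix(synth)
  mu <- colMeans(real)
  sd <- apply(real, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(real = sweep(sweep(real, 2, mu), 2, sd, "/"),
       synth = sweep(sweep(synth, 2, mu), 2, sd, "/"))
}

# Euclidean cross-distance matrix, rows of a vs rows of b.
cross_dist <- function(a, b) {
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

seeded_kmeans <- function(x, centers, seed, nstart = 10L) {
  set.seed(seed)
  fit <- tryCatch(suppressWarnings(
    stats::kmeans(x, centers = centers, nstart = nstart, iter.max = 50L)),
    error = function(e) NULL)
  if (is.null(fit))  # Hartigan-Wong can abort on tight/duplicated points
    fit <- tryCatch(suppressWarnings(
      stats::kmeans(x, centers = centers, nstart = nstart, iter.max = 50L,
                    algorithm = "Lloyd")),
      error = function(e) NULL)
  fit
}

select_features <- function(table, key_features) {
  df <- as.data.frame(table)
  if (is.null(key_features)) as.matrix(df)
  else as.matrix(df[, key_features, drop = FALSE])
}

#' Cluster-based k-anonymity score
#'
#' Clusters the table with k-means over the quasi-identifying key features at
#' several granularities (numbers of clusters) and reports the minimum
#' cluster occupancy across reliable granularities — the effective number of
#' records indistinguishable from the most exposed one. Granularities that
#' produce any cluster with fewer than `min_cluster` members (including
#' k-means failures on degenerate data) are skipped with a fallback note; if
#' no granularity is reliable the table is treated as a single cluster.
#'
#' @param table Numeric matrix or data.frame of encoded rows.
#' @param key_features Columns used as quasi-identifiers.
#' @param granularities Cluster counts to try (default 2, 5, 10, 15).
#' @param seed Seed for k-means initialization.
#' @param min_cluster Reliability threshold for cluster occupancy.
#' @return List with `score` (higher is safer), `per_granularity`,
#'   `fallbacks` (notes), `orientation`.
#' @export
cluster_k_anonymity <- function(table, key_features = colnames(table),
                                granularities = c(2, 5, 10, 15), seed = 1L,
                                min_cluster = 5L) {
  x <- select_features(table, key_features)
  if (nrow(x) < min(granularities))
    stop("fewer rows than the smallest granularity")
  per <- list(); notes <- character(0)
  for (g in granularities) {
    fit <- seeded_kmeans(x, g, seed)
    sizes <- if (is.null(fit)) integer(0) else tabulate(fit$cluster, g)
    if (is.null(fit) || any(sizes < min_cluster)) {
      notes <- c(notes, sprintf(
        "granularity %d skipped: %s", g,
        if (is.null(fit)) "clustering failed (degenerate data)"
        else sprintf("cluster with %d < %d members", min(sizes), min_cluster)))
      next
    }
    per[[as.character(g)]] <- min(sizes)
  }
  score <- if (length(per)) min(unlist(per)) else {
    notes <- c(notes, "no reliable granularity; table treated as one cluster")
    nrow(x)
  }
  list(score = score, per_granularity = per, fallbacks = notes,
       orientation = "higher_safer")
}

#' Cluster-based l-diversity score
#'
#' Within each reliable k-means cluster over the key features, counts the
#' distinct combinations of the sensitive columns; the score is the minimum
#' across clusters and granularities. A low score means some group of
#' look-alike records is nearly homogeneous in its sensitive attributes.
#'
#' @inheritParams cluster_k_anonymity
#' @param sensitive_columns Columns whose combinations must stay diverse.
#' @return List with `score` (higher is safer), `fallbacks`, `orientation`.
#' @export
l_diversity <- function(table, key_features, sensitive_columns,
                        granularities = c(2, 5, 10, 15), seed = 1L,
                        min_cluster = 5L) {
  stopifnot(length(sensitive_columns) >= 1L)
  df <- as.data.frame(table)
  x <- select_features(table, key_features)
  sens <- do.call(paste, c(df[, sensitive_columns, drop = FALSE], sep = "\r"))
  per <- list(); notes <- character(0)
  for (g in granularities) {
    fit <- seeded_kmeans(x, g, seed)
    sizes <- if (is.null(fit)) integer(0) else tabulate(fit$cluster, g)
    if (is.null(fit) || any(sizes < min_cluster)) {
      notes <- c(notes, sprintf("granularity %d skipped", g))
      next
    }
    per[[as.character(g)]] <-
      min(vapply(split(sens, fit$cluster), function(s) length(unique(s)),
                 integer(1)))
  }
  score <- if (length(per)) min(unlist(per)) else {
    notes <- c(notes, "no reliable granularity; table treated as one cluster")
    length(unique(sens))
  }
  list(score = score, fallbacks = notes, orientation = "higher_safer")
}

#' k-map score
#'
#' Models an adversary with external data: k-means is fitted on the real
#' table only, synthetic rows are assigned to the nearest real centroid, and
#' the score is the smallest synthetic occupancy over the real clusters — the
#' most vulnerable group.
#'
#' @inheritParams cluster_k_anonymity
#' @param real,synth Numeric matrices/data.frames on the same key features.
#' @return List with `score` (higher is safer), `fallbacks`, `orientation`.
#' @export
k_map <- function(real, synth, key_features = colnames(real),
                  granularities = c(2, 5, 10, 15), seed = 1L,
                  min_cluster = 5L) {
  xr <- select_features(real, key_features)
  xs <- select_features(synth, key_features)
  if (nrow(xs) == 0L) stop("empty synthetic table")
  per <- list(); notes <- character(0)
  for (g in granularities) {
    fit <- seeded_kmeans(xr, g, seed)
    sizes <- if (is.null(fit)) integer(0) else tabulate(fit$cluster, g)
    if (is.null(fit) || any(sizes < min_cluster)) {
      notes <- c(notes, sprintf("granularity %d skipped", g))
      next
    }
    assign_s <- max.col(-cross_dist(xs, fit$centers), ties.method = "first")
    per[[as.character(g)]] <- min(tabulate(assign_s, g))
  }
  score <- if (length(per)) min(unlist(per)) else {
    notes <- c(notes, "no reliable granularity; table treated as one cluster")
    nrow(xs)
  }
  list(score = score, fallbacks = notes, orientation = "higher_safer")
}

#' Delta-presence score
#'
#' For each real-fitted cluster, the fraction of distinct real sensitive
#' combinations that also appear among the synthetic rows assigned to the
#' same cluster; the score is the maximum over clusters and granularities, an
#' upper bound on presence disclosure. Lower is safer.
#'
#' @inheritParams k_map
#' @param sensitive_columns Sensitive columns compared between the tables.
#' @param real_df,synth_df Data.frames holding the sensitive columns (default:
#'   the tables themselves).
#' @return List with `score` in `[0, 1]` (lower is safer), `fallbacks`,
#'   `orientation`.
#' @export
delta_presence <- function(real, synth, key_features, sensitive_columns,
                           granularities = c(2, 5, 10, 15), seed = 1L,
                           min_cluster = 5L, real_df = as.data.frame(real),
                           synth_df = as.data.frame(synth)) {
  xr <- select_features(real, key_features)
  xs <- select_features(synth, key_features)
  if (nrow(xs) == 0L) stop("empty synthetic table")
  sens_r <- do.call(paste, c(real_df[, sensitive_columns, drop = FALSE], sep = "\r"))
  sens_s <- do.call(paste, c(synth_df[, sensitive_columns, drop = FALSE], sep = "\r"))
  per <- list(); notes <- character(0)
  for (g in granularities) {
    fit <- seeded_kmeans(xr, g, seed)
    sizes <- if (is.null(fit)) integer(0) else tabulate(fit$cluster, g)
    if (is.null(fit) || any(sizes < min_cluster)) {
      notes <- c(notes, sprintf("granularity %d skipped", g))
      next
    }
    assign_s <- max.col(-cross_dist(xs, fit$centers), ties.method = "first")
    ratios <- vapply(seq_len(g), function(cl) {
      rs <- unique(sens_r[fit$cluster == cl])
      ss <- unique(sens_s[assign_s == cl])
      mean(rs %in% ss)
    }, numeric(1))
    per[[as.character(g)]] <- max(ratios)
  }
  score <- if (length(per)) max(unlist(per)) else {
    notes <- c(notes, "no reliable granularity; table treated as one cluster")
    mean(unique(sens_r) %in% unique(sens_s))
  }
  list(score = score, fallbacks = notes, orientation = "lower_safer")
}

second_nearest_real <- function(xr) {
  d <- cross_dist(xr, xr)
  diag(d) <- Inf
  apply(d, 1, function(row) sort(row, partial = 2)[2])
}

#' Identifiability (re-identification) score
#'
#' Fraction of real records lying strictly closer to some synthetic record
#' than to their own second-nearest real neighbor, on the standardized
#' encoded features (standardization fitted on real only). Distance ties
#' count as "not closer". Lower is safer.
#'
#' @param real,synth Numeric matrices/data.frames with identical columns.
#' @return List with `score` in `[0, 1]` (lower is safer), `orientation`.
#' @export
identifiability_score <- function(real, synth) {
  if (nrow(as.data.frame(real)) < 2L) stop("need at least 2 real rows")
  st <- standardize_pair(real, synth)
  d_syn <- apply(cross_dist(st$real, st$synth), 1, min)
  d_real2 <- second_nearest_real(st$real)
  list(score = mean(d_syn < d_real2), orientation = "lower_safer")
}

#' Single-out score
#'
#' Probability of singling a real individual out of the synthetic release,
#' computed with the same closer-than-second-real-neighbor construction as
#' [identifiability_score()] and reported as a separate metric.
#'
#' @inheritParams identifiability_score
#' @return List with `score` (lower is safer), `orientation`.
#' @export
single_out_score <- function(real, synth) {
  res <- identifiability_score(real, synth)
  res
}

#' Density-based membership inference attack
#'
#' Scores each real record by the local density of synthetic points around it
#' (inverse distance to the k-th nearest synthetic neighbor) and asks whether
#' these scores separate training members from a disjoint holdout. Reports
#' the attack accuracy at the balanced (median) threshold and the rank-based
#' AUC; values near 0.5 mean the synthetic data reveal no membership signal.
#'
#' @param train_real,holdout_real Encoded matrices of members / non-members.
#' @param synth Encoded synthetic matrix.
#' @param neighbors Neighborhood size; default `ceiling(sqrt(nrow(synth)))`.
#' @return List with `accuracy`, `auc` (both lower-safer, 0.5 = chance),
#'   `neighbors`, `orientation`.
#' @export
mia_density <- function(train_real, holdout_real, synth, neighbors = NULL) {
  synth <- as.matrix(synth)
  if (is.null(neighbors)) neighbors <- ceiling(sqrt(nrow(synth)))
  if (neighbors >= nrow(synth)) stop("neighbors must be < nrow(synth)")
  st <- standardize_pair(rbind(as.matrix(train_real), as.matrix(holdout_real)),
                         synth)
  n_tr <- nrow(as.matrix(train_real))
  d <- cross_dist(st$real, st$synth)
  kd <- apply(d, 1, function(row) sort(row, partial = neighbors)[neighbors])
  score <- 1 / (kd + 1e-12)
  member <- c(rep(1L, n_tr), rep(0L, nrow(d) - n_tr))
  thr <- stats::median(score)
  acc <- mean((score > thr) == (member == 1L))
  r <- rank(score)
  n1 <- sum(member == 1L); n0 <- sum(member == 0L)
  auc <- (sum(r[member == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(accuracy = acc, auc = auc, neighbors = neighbors,
       orientation = "lower_safer")
}

modal_hit <- function(values, truth) {
  tab <- base::table(values)
  modes <- names(tab)[tab == max(tab)]
  if (truth %in% modes) 1 / length(modes) else 0
}

#' Correct attribution probability (CAP)
#'
#' Simulates an attacker who knows a record's key attributes and guesses its
#' sensitive attribute from the synthetic data. In `"zero"` mode only exact
#' key matches are used (no match contributes 0); in `"generalized"` mode the
#' nearest synthetic records by key similarity (Hamming distance over keys)
#' are used instead. The attacker guesses the modal sensitive value among the
#' matched synthetic rows; ties among modes share credit. Returns the mean
#' success probability and the complementary protection score.
#'
#' @param real,synth Cohort data.frames.
#' @param key_columns Categorical or discretized key columns.
#' @param sensitive_column Sensitive column to attribute.
#' @param mode `"zero"` or `"generalized"`.
#' @return List with `success` (lower is safer), `protection = 1 - success`,
#'   `mode`, `orientation`.
#' @export
cap_score <- function(real, synth, key_columns, sensitive_column,
                      mode = c("zero", "generalized")) {
  mode <- match.arg(mode)
  if (!sensitive_column %in% names(synth))
    stop(sprintf("sensitive column '%s' absent from synthetic data", sensitive_column))
  rk <- lapply(real[key_columns], as.character)
  sk <- lapply(synth[key_columns], as.character)
  sens_r <- as.character(real[[sensitive_column]])
  sens_s <- as.character(synth[[sensitive_column]])
  n <- nrow(real)
  succ <- numeric(n)
  if (length(key_columns) == 0L) {
    return(cap_no_keys(sens_r, sens_s))
  }
  keys_r <- do.call(paste, c(rk, sep = "\r"))
  keys_s <- do.call(paste, c(sk, sep = "\r"))
  for (i in seq_len(n)) {
    if (mode == "zero") {
      hit <- keys_s == keys_r[i]
      succ[i] <- if (any(hit)) modal_hit(sens_s[hit], sens_r[i]) else 0
    } else {
      dist <- Reduce(`+`, lapply(seq_along(key_columns), function(j)
        as.integer(sk[[j]] != rk[[j]][i])))
      hit <- dist == min(dist)
      succ[i] <- modal_hit(sens_s[hit], sens_r[i])
    }
  }
  list(success = mean(succ), protection = 1 - mean(succ), mode = mode,
       orientation = "lower_safer")
}

cap_no_keys <- function(sens_r, sens_s) {
  tab <- base::table(sens_s)
  modes <- names(tab)[tab == max(tab)]
  succ <- mean(vapply(sens_r, function(v)
    if (v %in% modes) 1 / length(modes) else 0, numeric(1)))
  list(success = succ, protection = 1 - succ, mode = "zero",
       orientation = "lower_safer")
}

#' Linkability score
#'
#' Splits the features into two disjoint subsets, finds for each real record
#' its nearest synthetic neighbor on each subset separately, and scores the
#' fraction of real records for which both searches point to the same
#' synthetic record — evidence that one synthetic individual links the two
#' attribute sets of one real person. Lower is safer.
#'
#' @param real,synth Numeric matrices/data.frames.
#' @param feature_split List of two disjoint character vectors of column
#'   names.
#' @return List with `score` (lower is safer), `orientation`.
#' @export
linkability_score <- function(real, synth, feature_split) {
  a <- feature_split[[1]]; b <- feature_split[[2]]
  if (length(intersect(a, b))) stop("feature subsets must be disjoint")
  if (nrow(as.data.frame(real)) < 2L)
    stop("need at least 2 real rows to contrast individuals")
  st <- standardize_pair(as.data.frame(real)[, c(a, b), drop = FALSE],
                         as.data.frame(synth)[, c(a, b), drop = FALSE])
  na <- length(a)
  da <- cross_dist(st$real[, seq_len(na), drop = FALSE],
                   st$synth[, seq_len(na), drop = FALSE])
  db <- cross_dist(st$real[, -seq_len(na), drop = FALSE],
                   st$synth[, -seq_len(na), drop = FALSE])
  nn_a <- max.col(-da, ties.method = "first")
  nn_b <- max.col(-db, ties.method = "first")
  list(score = mean(nn_a == nn_b), orientation = "lower_safer")
}

#' Inference risk
#'
#' Probability of inferring a hidden sensitive attribute from partial
#' knowledge, computed as generalized correct attribution probability for the
#' declared known/secret split. With no known columns the attacker falls back
#' to the best constant guess (the modal class).
#'
#' @param real,synth Cohort data.frames.
#' @param known_columns Columns the attacker knows.
#' @param secret_column Column the attacker infers.
#' @return List with `success` (lower is safer), `protection`, `orientation`.
#' @export
inference_risk <- function(real, synth, known_columns, secret_column) {
  res <- cap_score(real, synth, known_columns, secret_column,
                   mode = if (length(known_columns)) "generalized" else "zero")
  res
}

#' Match configuration for the heuristic match-rate audit
#'
#' @param spans Named numeric vector: per-variable absolute tolerance
#'   (numeric/date columns) or 0 for exact matching (categorical columns).
#' @param label Configuration label.
#' @return An object of class `match_config`.
#' @export
match_config <- function(spans, label = "") {
  spans <- unlist(spans)
  if (any(spans < 0)) stop("spans must be >= 0")
  structure(list(spans = spans, label = label), class = "match_config")
}

row_matches_any <- function(target_row, pool, spans, cols) {
  ok <- rep(TRUE, nrow(pool))
  for (cn in cols) {
    tv <- target_row[[cn]]
    pv <- pool[[cn]]
    if (is.numeric(pv) || inherits(pv, "Date")) {
      this <- if (is.na(tv)) is.na(pv)
              else !is.na(pv) & abs(as.numeric(pv) - as.numeric(tv)) <= spans[[cn]]
    } else {
      this <- if (is.na(tv)) is.na(pv) else !is.na(pv) & as.character(pv) == as.character(tv)
    }
    ok <- ok & this
    if (!any(ok)) return(FALSE)
  }
  any(ok)
}

#' Synthetic-to-real match rate
#'
#' Fraction of synthetic rows that approximately match at least one real row
#' on all variables of the configuration simultaneously — numeric and date
#' variables within their span, categorical exactly, missing matching only
#' missing.
#'
#' @param real,synth Cohort data.frames.
#' @param config A [match_config()].
#' @return List with `rate` (lower is safer for synthetic data), `label`,
#'   `orientation`.
#' @export
match_rate <- function(real, synth, config) {
  stopifnot(inherits(config, "match_config"))
  cols <- names(config$spans)
  missing_cols <- setdiff(cols, intersect(names(real), names(synth)))
  if (length(missing_cols))
    stop(sprintf("span declared for absent column '%s'", missing_cols[1L]))
  hits <- vapply(seq_len(nrow(synth)), function(i)
    row_matches_any(synth[i, cols, drop = FALSE], real, config$spans, cols),
    logical(1))
  list(rate = mean(hits), label = config$label, orientation = "lower_safer")
}

#' Real-to-real baseline match rate
#'
#' The same matching logic applied within the real data, excluding matches to
#' the same individual: the likelihood of coincidental matches between
#' different people, the baseline a synthetic match rate is judged against.
#'
#' @param real Cohort data.frame.
#' @param config A [match_config()].
#' @param id_column Column identifying individuals.
#' @return List with `rate`, `label`, `orientation = "baseline"`.
#' @export
baseline_match_rate <- function(real, config, id_column = "id") {
  stopifnot(inherits(config, "match_config"))
  if (!id_column %in% names(real))
    stop(sprintf("id column '%s' not found", id_column))
  cols <- names(config$spans)
  ids <- as.character(real[[id_column]])
  hits <- vapply(seq_len(nrow(real)), function(i) {
    pool <- real[ids != ids[i], , drop = FALSE]
    if (!nrow(pool)) return(FALSE)
    row_matches_any(real[i, cols, drop = FALSE], pool, config$spans, cols)
  }, logical(1))
  list(rate = mean(hits), label = config$label, orientation = "baseline")
}

#' Full disclosure-risk report
#'
#' Runs the whole metric suite on an encoded real/synthetic pair and collects
#' every score with its orientation and any clustering fallback notes.
#'
#' @param real_encoded,synth_encoded Encoded numeric matrices.
#' @param real_cohort,synth_cohort Raw cohorts for attribution metrics.
#' @param key_features Encoded columns used as quasi-identifiers (default:
#'   all).
#' @param key_columns,sensitive_column Raw columns for CAP-style metrics
#'   (skipped when `NULL`).
#' @param granularities,seed Passed to the clustering metrics.
#' @return A list of class `privacy_report`.
#' @export
privacy_report <- function(real_encoded, synth_encoded,
                           real_cohort = NULL, synth_cohort = NULL,
                           key_features = colnames(real_encoded),
                           key_columns = NULL, sensitive_column = NULL,
                           granularities = c(2, 5, 10, 15), seed = 1L) {
  rep <- list(
    k_anonymity_real = cluster_k_anonymity(real_encoded, key_features,
                                           granularities, seed),
    k_anonymity_synth = cluster_k_anonymity(synth_encoded, key_features,
                                            granularities, seed),
    k_map = k_map(real_encoded, synth_encoded, key_features, granularities, seed),
    identifiability = identifiability_score(real_encoded, synth_encoded),
    single_out = single_out_score(real_encoded, synth_encoded))
  half <- floor(length(key_features) / 2)
  if (half >= 1 && length(key_features) >= 2)
    rep$linkability <- linkability_score(
      real_encoded, synth_encoded,
      list(key_features[seq_len(half)], key_features[-seq_len(half)]))
  if (!is.null(real_cohort) && !is.null(sensitive_column)) {
    rep$cap_zero <- cap_score(real_cohort, synth_cohort, key_columns,
                              sensitive_column, "zero")
    rep$cap_generalized <- cap_score(real_cohort, synth_cohort, key_columns,
                                     sensitive_column, "generalized")
    rep$inference_risk <- inference_risk(real_cohort, synth_cohort,
                                         key_columns, sensitive_column)
  }
  structure(rep, class = "privacy_report")
}

#' @export
print.privacy_report <- function(x, ...) {
  for (nm in names(x)) {
    v <- x[[nm]]
    val <- v$score %||% v$success %||% v$auc %||% v$rate
    cat(sprintf("  %-18s %8.4f  (%s)\n", nm, val, v$orientation))
  }
  invisible(x)
}
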