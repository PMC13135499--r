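#' Encode calendar dates as day counts
#'
#' Converts dates to signed integer numbers of days since a fixed reference
#' point, preserving missing values; the first step of the structured
#' preprocessing pipeline.
#'
#' @param dates A `Date` vector (or ISO-8601 strings).
#' @param reference_date The fixed reference point.
#' @return Integer day counts, `NA` where the input was missing.
#' @export
encode_dates <- function(dates, reference_date) {
  if (is.character(dates)) {
    d <- as.Date(dates, format = "%Y-%m-%d")
    if (any(is.na(d) & !is.na(dates)))
      stop("malformed date among non-missing values")
    dates <- d
  }
  as.integer(dates - as.Date(reference_date))
}

# Empirical quantile grid for one column. Levels use the (i - 0.5)/n dialect
# on the n (imputed) observations; tied values collapse to one grid point at
# the mean of their constituent levels, so the grid is strictly increasing in
# both value and level and never touches exactly 0 or 1.
fit_quantile_grid <- function(x) {
  stopifnot(!anyNA(x), length(x) >= 1L)
  n <- length(x)
  lev <- (rank(x, ties.method = "average") - 0.5) / n
  ord <- !duplicated(x)
  values <- x[ord]
  levels <- lev[ord]
  o <- order(values)
  list(values = values[o], levels = levels[o])
}

#' Map values through a fitted empirical quantile grid
#'
#' Deterministic, monotone non-decreasing transform built from the empirical
#' cumulative distribution of the fitted data: grid points map to their
#' assigned quantile level, values between grid points interpolate linearly,
#' and out-of-range values clamp to the boundary levels. With
#' `output = "gaussian"` the uniform level is passed through the standard
#' normal quantile function.
#'
#' @param values Numeric values to transform.
#' @param grid A grid from the fitted transform (`list(values, levels)`).
#' @param output `"uniform"` (levels in (0, 1)) or `"gaussian"`.
#' @return Transformed values; `NA` preserved.
#' @export
quantile_transform <- function(values, grid, output = c("uniform", "gaussian")) {
  output <- match.arg(output)
  if (length(grid$values) == 0L) stop("empty quantile grid")
  p <- if (length(grid$values) == 1L)
    ifelse(is.na(values), NA_real_, grid$levels)
  else stats::approx(grid$values, grid$levels, xout = values, rule = 2)$y
  if (output == "gaussian") stats::qnorm(p) else p
}

#' @rdname quantile_transform
#' @param p Transformed values to map back to the original scale.
#' @export
quantile_inverse <- function(p, grid, output = c("uniform", "gaussian")) {
  output <- match.arg(output)
  if (length(grid$values) == 0L) stop("empty quantile grid")
  if (output == "gaussian") p <- stats::pnorm(p)
  if (length(grid$values) == 1L)
    return(ifelse(is.na(p), NA_real_, grid$values))
  stats::approx(grid$levels, grid$values, xout = p, rule = 2)$y
}

onehot_name <- function(column, level) paste0(column, "=", level)
PLACEHOLDER <- "Unknown"

#' Fit the bidirectional preprocessing pipeline
#'
#' The structured (level-3) variant for high-missingness data: dates are
#' encoded as day counts; continuous and date columns are median-imputed,
#' quantile-transformed through their empirical CDF, and accompanied by a
#' binary missingness indicator (suffix `_q_m`) flagging originally missing
#' cells; binary and categorical columns get a dedicated `"Unknown"`
#' placeholder level and one-hot encoding. Identifier columns pass through
#' unencoded (kept aside for inversion). The fitted transform is exactly
#' invertible via [inverse_transform()].
#'
#' The simpler level-1/2 variant ([fit_transform_level12()]) instead imputes
#' continuous and date columns with the constant -1 and adds no indicators.
#'
#' @param cohort A typed cohort conforming to `config`.
#' @param config A [study_config()].
#' @param output Output law of the quantile transform, `"uniform"` (default)
#'   or `"gaussian"`.
#' @param indicator_threshold Missingness fraction above which a continuous or
#'   date column receives an indicator. The default 0 flags every such column;
#'   set to e.g. 0.5 to flag only high-missingness columns.
#' @return A list of class `encoded_cohort`: `matrix` (numeric, rows x encoded
#'   columns), `provenance` (data.frame mapping encoded columns to source
#'   column and kind), `transform` (the `fitted_transform`).
#' @export
fit_transform <- function(cohort, config, output = c("uniform", "gaussian"),
                          indicator_threshold = 0) {
  output <- match.arg(output)
  build_transform(cohort, config, variant = "level3", output = output,
                  indicator_threshold = indicator_threshold)
}

#' @rdname fit_transform
#' @export
fit_transform_level12 <- function(cohort, config) {
  build_transform(cohort, config, variant = "level12", output = "uniform",
                  indicator_threshold = 1)
}

build_transform <- function(cohort, config, variant, output,
                            indicator_threshold) {
  stopifnot(inherits(config, "study_config"))
  n <- nrow(cohort)
  cols <- list()        # per-column transform state
  enc <- list()         # encoded numeric columns
  prov <- list()        # provenance rows
  ids <- list()
  add <- function(name, values, source, kind) {
    enc[[name]] <<- values
    prov[[length(prov) + 1L]] <<- data.frame(encoded = name, source = source,
                                             kind = kind,
                                             stringsAsFactors = FALSE)
  }
  for (name in names(config$columns)) {
    cs <- config$columns[[name]]
    x <- cohort[[name]]
    if (cs$role == "identifier") {
      ids[[name]] <- as.character(x)
      cols[[name]] <- list(role = "identifier")
      next
    }
    if (cs$role %in% c("continuous", "date")) {
      raw <- if (cs$role == "date")
        as.numeric(encode_dates(x, config$reference_date)) else as.numeric(x)
      miss <- is.na(raw)
      if (all(miss)) stop(sprintf("column '%s' has no observed values", name))
      if (variant == "level12") {
        cols[[name]] <- list(role = cs$role, variant = "level12",
                             observed = sort(unique(raw[!miss])))
        add(name, ifelse(miss, -1, raw), name, "passthrough")
        next
      }
      med <- stats::median(raw[!miss])
      imputed <- ifelse(miss, med, raw)
      grid <- fit_quantile_grid(imputed)
      flag <- mean(miss) >= indicator_threshold
      st <- list(role = cs$role, variant = "level3", median = med,
                 grid = grid, flag = flag,
                 flag_name = if (flag) paste0(name, "_q_m"))
      cols[[name]] <- st
      add(paste0(name, "_q"), quantile_transform(imputed, grid, output),
          name, "quantile_value")
      if (flag) add(st$flag_name, as.numeric(miss), name, "missing_flag")
    } else {
      levels <- c(cs$categories, PLACEHOLDER)
      xi <- as.character(x)
      xi[is.na(xi)] <- PLACEHOLDER
      cols[[name]] <- list(role = cs$role, levels = levels)
      for (lev in levels)
        add(onehot_name(name, lev), as.numeric(xi == lev), name, "onehot_level")
    }
  }
  mat <- if (length(enc)) do.call(cbind, enc) else matrix(numeric(0), n, 0)
  colnames(mat) <- names(enc)
  transform <- structure(list(columns = cols,
                              reference_date = config$reference_date,
                              variant = variant, output = output,
                              indicator_threshold = indicator_threshold,
                              identifiers = ids, n_fit = n),
                         class = "fitted_transform")
  structure(list(matrix = mat,
                 provenance = do.call(rbind, prov),
                 transform = transform),
            class = "encoded_cohort")
}

#' @export
print.fitted_transform <- function(x, ...) {
  cat(sprintf("fitted_transform (%s, %s output): %d columns fitted on %d rows\n",
              x$variant, x$output, length(x$columns), x$n_fit))
  invisible(x)
}

#' Invert the preprocessing pipeline
#'
#' Restores original column names, order, types and missing cells from an
#' encoded matrix: quantile columns map back through the fitted grid (dates
#' additionally from day counts to calendar dates), rows whose missingness
#' indicator is at least 0.5 are restored to missing, and one-hot blocks are
#' decoded by argmax with the placeholder level mapping to missing. In the
#' level-1/2 variant a -1 maps back to missing only when -1 was not an
#' observed value of that column.
#'
#' @param encoded An `encoded_cohort`, or a bare numeric matrix whose columns
#'   match the transform's encoded schema.
#' @param transform The `fitted_transform` (taken from `encoded` if missing).
#' @param config The [study_config()] used at fit time.
#' @return A typed cohort `data.frame`.
#' @export
inverse_transform <- function(encoded, transform = NULL, config) {
  if (inherits(encoded, "encoded_cohort")) {
    if (is.null(transform)) transform <- encoded$transform
    mat <- encoded$matrix
  } else mat <- encoded
  stopifnot(inherits(transform, "fitted_transform"))
  n <- nrow(mat)
  out <- list()
  for (name in names(config$columns)) {
    st <- transform$columns[[name]]
    if (is.null(st)) stop(sprintf("transform has no state for column '%s'", name))
    if (st$role == "identifier") {
      idv <- transform$identifiers[[name]]
      out[[name]] <- if (!is.null(idv) && length(idv) == n) idv
                     else as.character(seq_len(n))
      next
    }
    if (st$role %in% c("continuous", "date")) {
      if (identical(st$variant, "level12")) {
        if (!name %in% colnames(mat))
          stop(sprintf("encoded matrix lacks column '%s'", name))
        v <- mat[, name]
        if (!(-1 %in% st$observed)) v[v == -1] <- NA
      } else {
        qn <- paste0(name, "_q")
        if (!qn %in% colnames(mat))
          stop(sprintf("encoded matrix lacks column '%s'", qn))
        v <- quantile_inverse(mat[, qn], st$grid, transform$output)
        if (st$flag) {
          if (!st$flag_name %in% colnames(mat))
            stop(sprintf("encoded matrix lacks flag column '%s'", st$flag_name))
          v[mat[, st$flag_name] >= 0.5] <- NA
        }
      }
      out[[name]] <- if (st$role == "date")
        as.Date(round(v), origin = transform$reference_date) else v
    } else {
      block <- vapply(st$levels, function(lev) onehot_name(name, lev),
                      character(1))
      if (!all(block %in% colnames(mat)))
        stop(sprintf("encoded matrix lacks one-hot block for '%s'", name))
      sub <- mat[, block, drop = FALSE]
      pick <- st$levels[max.col(sub, ties.method = "first")]
      pick[pick == PLACEHOLDER] <- NA
      out[[name]] <- pick
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Expected encoded column count
#'
#' Dimensional accounting for the level-3 encoding: one quantile column plus
#' (optionally) one indicator per continuous/date column, and one column per
#' category plus the placeholder for binary/categorical columns.
#'
#' @param encoded An `encoded_cohort`.
#' @return Integer count, equal to `ncol(encoded$matrix)`.
#' @export
encoded_width <- function(encoded) {
  tr <- encoded$transform
  sum(vapply(tr$columns, function(st) {
    switch(st$role,
      identifier = 0L,
      continuous = ,
      date = if (identical(st$variant, "level12")) 1L
             else 1L + as.integer(isTRUE(st$flag)),
      binary = ,
      categorical = length(st$levels))
  }, integer(1)))
}
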