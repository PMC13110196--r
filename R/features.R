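#' Per-series scalar features
#'
#' The six summary features that characterise one subject's time series.
#' Each returns `NA` (the undefined marker) when its precondition fails:
#'
#' * `ts_average()`: arithmetic mean of the non-missing values (>= 1
#'   value). Sensitive to systematic shifts, e.g. lab calibration bias.
#' * `ts_sd()`: sample standard deviation, denominator `n - 1` (>= 2
#'   values). Sensitive to implausible fluctuations.
#' * `ts_range()`: max minus min (>= 2 values; a single value carries no
#'   dispersion information, so length-one series are undefined rather
#'   than 0). Sensitive to magnitude/unit errors.
#' * `unique_value_ratio()`: distinct non-missing values divided by the
#'   number of non-missing values (>= 1 value). Equality is exact floating
#'   equality: rounding in the data is precisely the signal sought. Low
#'   values indicate duplication or coarse rounding.
#' * `ts_autocorrelation()`: Pearson correlation between the series and
#'   its lag-1 shift over consecutive schedule positions where both values
#'   are present; needs >= 2 such pairs and non-zero variance in both
#'   lagged subvectors. Sensitive to artificial linearity (e.g. a site
#'   adding a constant to the previous measurement).
#'
#' @param series numeric vector in schedule order, `NA` = missing.
#' @return A single numeric value or `NA`.
#' @export
ts_average <- function(series) {
  x <- series[!is.na(series)]
  if (length(x) < 1L) return(NA_real_)
  mean(x)
}

#' @rdname ts_average
#' @export
ts_sd <- function(series) {
  x <- series[!is.na(series)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x)
}

#' @rdname ts_average
#' @export
ts_range <- function(series) {
  x <- series[!is.na(series)]
  if (length(x) < 2L) return(NA_real_)
  max(x) - min(x)
}

#' @rdname ts_average
#' @export
unique_value_ratio <- function(series) {
  x <- series[!is.na(series)]
  if (length(x) < 1L) return(NA_real_)
  length(unique(x)) / length(x)
}

#' @rdname ts_average
#' @export
ts_autocorrelation <- function(series) {
  n <- length(series)
  if (n < 2L) return(NA_real_)
  a <- series[-n]
  b <- series[-1L]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) return(NA_real_)
  a <- a[ok]
  b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Local outlier factor of each series in a group
#'
#' Density-ratio outlier score of every subject's (imputed) series vector
#' among all series of the group, with Euclidean distances and
#' neighbourhood size `k`. Unlike the other five features, LOF is context
#' dependent: a subject's score depends on the other series in the study.
#' Scores near 1 indicate inliers (or suspicious uniformity when an
#' entire site sits at ~1), scores well above 1 indicate series in
#' sparser regions than their neighbours.
#'
#' Missing entries are imputed with the per-visit median across the
#' group's subjects before distances are computed; grouping guarantees at
#' most the configured missing ratio per subject. Reachability distances
#' are floored at `1e-12` so exactly duplicated series do not divide by
#' zero (a group of identical series scores 1 everywhere).
#'
#' @param group_values subjects x visits numeric matrix (`NA` = missing).
#' @param k neighbourhood size; default `min(20, n - 1)`.
#' @return Numeric vector of LOF scores, one per row; all `NA` when fewer
#'   than `k + 1` subjects are available.
#' @export
lof_scores <- function(group_values, k = NULL) {
  n <- nrow(group_values)
  if (is.null(k)) k <- min(20L, n - 1L)
  out <- rep(NA_real_, n)
  names(out) <- rownames(group_values)
  if (n < 2L || k < 1L || n < k + 1L) {
    return(out)
  }
  m <- impute_visit_median(group_values)
  d <- as.matrix(stats::dist(m))

  kdist <- numeric(n)
  neigh <- vector("list", n)
  for (i in seq_len(n)) {
    di <- d[i, -i]
    kdist[i] <- sort(di, partial = k)[k]
    nb <- which(d[i, ] <= kdist[i])
    neigh[[i]] <- nb[nb != i] # all points within k-distance (ties included)
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    reach <- pmax(kdist[neigh[[i]]], d[i, neigh[[i]]], 1e-12)
    lrd[i] <- 1 / mean(reach)
  }
  for (i in seq_len(n)) {
    out[i] <- mean(lrd[neigh[[i]]]) / lrd[i]
  }
  out
}

#' Feature matrix of a time-series group
#'
#' Applies the enabled features to every subject of a group and returns a
#' tibble with one row per subject and one column per feature, plus
#' `subject_id` and `site_id`. Undefined values are `NA`. For groups of a
#' single visit only the average and LOF are meaningful; standard
#' deviation, range, unique-value ratio and autocorrelation are reported
#' as `NA`.
#'
#' @param group a `ts_group`.
#' @param enabled character subset of
#'   `c("average", "sd", "range", "unique_value_ratio", "autocorrelation",
#'   "lof")`; default all six.
#' @param lof_k LOF neighbourhood size passed to [lof_scores()].
#' @return A `feature_matrix` tibble with attributes `group_id` and
#'   `parameter`.
#' @export
compute_features <- function(group, enabled = feature_names(), lof_k = NULL) {
  enabled <- unique(enabled)
  if (!length(enabled)) {
    rlang::abort("at least one feature must be enabled",
                 class = "sitespotter_config_error")
  }
  bad <- setdiff(enabled, feature_names())
  if (length(bad)) {
    rlang::abort(sprintf("unknown feature(s): %s", paste(bad, collapse = ", ")),
                 class = "sitespotter_config_error")
  }
  vals <- group$values
  n_visits <- ncol(vals)
  out <- tibble::tibble(
    subject_id = group$subject_ids,
    site_id = unname(group$site_ids)
  )
  row_apply <- function(f) apply(vals, 1L, f)
  for (f in enabled) {
    out[[f]] <- switch(
      f,
      average = row_apply(ts_average),
      sd = if (n_visits < 2L) NA_real_ else row_apply(ts_sd),
      range = if (n_visits < 2L) NA_real_ else row_apply(ts_range),
      unique_value_ratio = if (n_visits < 2L) NA_real_
                           else row_apply(unique_value_ratio),
      autocorrelation = if (n_visits < 2L) NA_real_
                        else row_apply(ts_autocorrelation),
      lof = unname(lof_scores(vals, k = lof_k))
    )
  }
  structure(out, class = c("feature_matrix", class(out)),
            group_id = group$group_id, parameter = group$parameter)
}

#' @rdname compute_features
#' @export
feature_names <- function() {
  c("average", "sd", "range", "unique_value_ratio", "autocorrelation", "lof")
}
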