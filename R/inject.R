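#' Define a site-anomaly injection scenario
#'
#' An `anomaly_scenario` is the recipe for one simulated site-level data
#' distortion: which transformation to apply (named after the feature it
#' pairs with), its intensity (`degree`), the affected parameter, the
#' target sites (by default three sites drawn at random) and the seed
#' that makes the injection reproducible.
#'
#' @param study the `study` the scenario applies to (used to draw and
#'   validate target sites).
#' @param anomaly_type one of `"average"`, `"sd"`, `"range"`,
#'   `"unique_value_ratio"`, `"autocorrelation"`, `"lof"`.
#' @param degree non-negative intensity. For `"unique_value_ratio"` and
#'   `"lof"` it is a ratio, clamped to `[0, 1]`.
#' @param parameter measurement parameter the anomaly targets.
#' @param target_sites explicit site ids; default `NULL` draws `n_sites`
#'   sites uniformly at random under `seed`.
#' @param n_sites number of sites to draw when `target_sites` is `NULL`.
#' @param seed integer seed for site selection and the stochastic parts
#'   of the transformations.
#' @return An `anomaly_scenario` list.
#' @export
anomaly_scenario <- function(study, anomaly_type, degree, parameter,
                             target_sites = NULL, n_sites = 3L, seed = 1L) {
  anomaly_type <- rlang::arg_match(anomaly_type, feature_names())
  if (degree < 0) {
    rlang::abort("degree must be >= 0", class = "sitespotter_config_error")
  }
  if (!parameter %in% study_parameters(study)) {
    rlang::abort(sprintf("unknown parameter '%s'", parameter),
                 class = "sitespotter_config_error")
  }
  sites <- study_sites(study)
  if (is.null(target_sites)) {
    n_sites <- min(n_sites, length(sites))
    target_sites <- withr::with_seed(mix_seed(seed, "target-sites"),
                                     sample(sites, n_sites))
  }
  if (!length(target_sites) || !all(target_sites %in% sites)) {
    rlang::abort("target_sites must be a non-empty subset of the study's sites",
                 class = "sitespotter_config_error")
  }
  structure(
    list(anomaly_type = anomaly_type, degree = degree, parameter = parameter,
         target_sites = sort(target_sites), seed = as.integer(seed)),
    class = "anomaly_scenario"
  )
}

# indices of injectable records plus per-site pre-injection means; the
# "site mean" is the mean of all non-missing values of the parameter at
# the site, so degrees stay comparable across parameters with different
# units
injection_context <- function(study, scenario) {
  rec <- study$records
  in_param <- rec$parameter == scenario$parameter & !is.na(rec$value)
  site_means <- tapply(rec$value[in_param], rec$site_id[in_param], mean)
  empty <- setdiff(scenario$target_sites, names(site_means))
  if (length(empty)) {
    rlang::warn(sprintf("site(s) with no data for '%s' skipped: %s",
                        scenario$parameter, paste(empty, collapse = ", ")))
  }
  idx <- which(in_param & rec$site_id %in% scenario$target_sites)
  idx <- idx[order(rec$subject_id[idx], rec$visit_index[idx],
                   !rec$scheduled[idx])]
  list(idx = idx, site_means = site_means)
}

#' Inject a site-level anomaly
#'
#' Applies the scenario's transformation to the non-missing values of the
#' target parameter at the target sites, leaving every other site (and
#' all structure: record count, missingness pattern, visit grid)
#' untouched. `inject_anomaly()` dispatches on the anomaly type; the six
#' `inject_*()` functions implement the transformations, each paired with
#' the feature it is designed to perturb (with site mean `m`, degree `d`):
#'
#' * `inject_average()`: `x' = x + m * d` — a systematic shift.
#' * `inject_sd()`: `x' = x + s * m * d` with sign `s` drawn uniformly
#'   from `{-1, +1}` per observation — inflates spread, mean preserved in
#'   expectation.
#' * `inject_range()`: one uniformly chosen visit per subject gets
#'   `x' = x + s * |m| * d` — a single outlying point.
#' * `inject_unique()`: a fraction `d` of each subject's later
#'   observations is overwritten with the subject's first observed value
#'   (round-half-up of `d * (n - 1)` replacements; the first observation
#'   itself is kept) — duplication.
#' * `inject_autocorrelation()`: `x'_t = x_t + d * x_{t-1}` using the
#'   original predecessor at schedule position `t - 1`; first visits and
#'   values with a missing predecessor are unchanged — artificial
#'   trending.
#' * `inject_lof()`: a fraction `d` of the target sites' subjects have
#'   their series redrawn from a randomly chosen non-normal distribution
#'   (uniform over the subject's range, exponential, near-constant, or a
#'   min/max two-point mixture), re-anchored to the subject's original
#'   mean (exactly) and, except for the near-constant pool, original
#'   range — distributional distortion.
#'
#' A degree of 0 is the identity for every type, and a fixed scenario
#' seed yields a bit-identical result.
#'
#' @param study a (cleaned) `study`.
#' @param scenario an [anomaly_scenario()].
#' @return The transformed `study`.
#' @export
inject_anomaly <- function(study, scenario) {
  switch(scenario$anomaly_type,
    average = inject_average(study, scenario),
    sd = inject_sd(study, scenario),
    range = inject_range(study, scenario),
    unique_value_ratio = inject_unique(study, scenario),
    autocorrelation = inject_autocorrelation(study, scenario),
    lof = inject_lof(study, scenario)
  )
}

#' @rdname inject_anomaly
#' @export
inject_average <- function(study, scenario) {
  ctx <- injection_context(study, scenario)
  rec <- study$records
  m <- ctx$site_means[rec$site_id[ctx$idx]]
  rec$value[ctx$idx] <- rec$value[ctx$idx] + m * scenario$degree
  new_study(rec, validate = FALSE)
}

#' @rdname inject_anomaly
#' @export
inject_sd <- function(study, scenario) {
  ctx <- injection_context(study, scenario)
  rec <- study$records
  m <- ctx$site_means[rec$site_id[ctx$idx]]
  signs <- withr::with_seed(mix_seed(scenario$seed, "sd-signs"),
                            sample(c(-1, 1), length(ctx$idx), replace = TRUE))
  rec$value[ctx$idx] <- rec$value[ctx$idx] + signs * m * scenario$degree
  new_study(rec, validate = FALSE)
}

#' @rdname inject_anomaly
#' @export
inject_range <- function(study, scenario) {
  ctx <- injection_context(study, scenario)
  rec <- study$records
  by_subject <- split(ctx$idx, rec$subject_id[ctx$idx])
  withr::with_seed(mix_seed(scenario$seed, "range-outliers"), {
    for (idx in by_subject) {
      pick <- if (length(idx) == 1L) idx else sample(idx, 1L)
      s <- sample(c(-1, 1), 1L)
      m <- ctx$site_means[rec$site_id[pick]]
      rec$value[pick] <- rec$value[pick] + s * abs(m) * scenario$degree
    }
  })
  new_study(rec, validate = FALSE)
}

#' @rdname inject_anomaly
#' @export
inject_unique <- function(study, scenario) {
  ratio <- min(max(scenario$degree, 0), 1)
  ctx <- injection_context(study, scenario)
  rec <- study$records
  by_subject <- split(ctx$idx, rec$subject_id[ctx$idx])
  withr::with_seed(mix_seed(scenario$seed, "unique-dups"), {
    for (idx in by_subject) {
      idx <- idx[order(rec$visit_index[idx])]
      first_val <- rec$value[idx[1L]]
      rest <- idx[-1L]
      n_rep <- floor(ratio * length(rest) + 0.5) # round half up
      if (n_rep > 0L) {
        pick <- if (length(rest) == 1L) rest else sample(rest, n_rep)
        rec$value[pick] <- first_val
      }
    }
  })
  new_study(rec, validate = FALSE)
}

#' @rdname inject_anomaly
#' @export
inject_autocorrelation <- function(study, scenario) {
  ctx <- injection_context(study, scenario)
  rec <- study$records
  idx <- ctx$idx
  # original predecessor value at visit_index - 1, same subject, if present
  key <- paste(rec$subject_id, rec$parameter, rec$visit_index, rec$scheduled)
  pred_key <- paste(rec$subject_id[idx], rec$parameter[idx],
                    rec$visit_index[idx] - 1L, rec$scheduled[idx])
  pred_pos <- match(pred_key, key[idx])
  pred_val <- rec$value[idx][pred_pos] # NA when no predecessor record
  has_pred <- !is.na(pred_val)
  rec$value[idx[has_pred]] <- rec$value[idx[has_pred]] +
    scenario$degree * pred_val[has_pred]
  new_study(rec, validate = FALSE)
}

#' @rdname inject_anomaly
#' @export
inject_lof <- function(study, scenario) {
  ratio <- min(max(scenario$degree, 0), 1)
  ctx <- injection_context(study, scenario)
  rec <- study$records
  by_subject <- split(ctx$idx, rec$subject_id[ctx$idx])
  subjects <- sort(names(by_subject))
  n_aff <- floor(ratio * length(subjects) + 0.5)
  withr::with_seed(mix_seed(scenario$seed, "lof-transform"), {
    affected <- if (n_aff >= length(subjects)) subjects
                else if (n_aff == 0L) character(0)
                else sample(subjects, n_aff)
    for (sj in affected) {
      idx <- by_subject[[sj]]
      x <- rec$value[idx]
      n <- length(x)
      mean0 <- mean(x)
      min0 <- min(x)
      max0 <- max(x)
      rng0 <- max0 - min0
      pool <- sample(c("uniform", "exponential", "constant", "two_point"), 1L)
      z <- switch(pool,
        uniform = stats::runif(n, min0, max0),
        exponential = stats::rexp(n, 1),
        constant = mean0 * (1 + 0.01 * stats::runif(n, -1, 1)),
        two_point = sample(c(min0, max0), n, replace = TRUE)
      )
      if (pool != "constant") {
        rngz <- max(z) - min(z)
        if (rngz > 0 && rng0 > 0) z <- (z - mean(z)) * (rng0 / rngz)
        else z <- z - mean(z)
        z <- z + mean0
      }
      rec$value[idx] <- z
    }
  })
  new_study(rec, validate = FALSE)
}
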