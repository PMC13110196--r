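#' Grouping configuration
#'
#' Parameters of the equal-length time-series group search: the minimum
#' number of eligible subjects a group must reach (default 25), the
#' maximum per-subject fraction of missing visits (default 0.30), and the
#' minimum relative gain in eligible subjects (default 0.20, i.e. 20%)
#' that justifies accepting an additional, shorter group.
#'
#' @param min_group_size integer >= 1.
#' @param max_missing_ratio fraction in `[0, 1]`.
#' @param improvement_ratio strictly positive fraction.
#' @return A `grouping_config` list.
#' @export
grouping_config <- function(min_group_size = 25L, max_missing_ratio = 0.30,
                            improvement_ratio = 0.20) {
  if (min_group_size < 1) {
    rlang::abort("min_group_size must be >= 1", class = "sitespotter_config_error")
  }
  if (max_missing_ratio < 0 || max_missing_ratio > 1) {
    rlang::abort("max_missing_ratio must lie in [0, 1]",
                 class = "sitespotter_config_error")
  }
  if (improvement_ratio <= 0) {
    rlang::abort("improvement_ratio must be > 0", class = "sitespotter_config_error")
  }
  structure(
    list(min_group_size = as.integer(min_group_size),
         max_missing_ratio = max_missing_ratio,
         improvement_ratio = improvement_ratio),
    class = "grouping_config"
  )
}

# subjects x visits matrix of scheduled values for one parameter;
# NA = visit absent or value missing
param_matrix <- function(study, parameter, visit_indices = NULL) {
  rec <- study$records
  if (!parameter %in% rec$parameter) {
    rlang::abort(sprintf("unknown parameter '%s'", parameter),
                 class = "sitespotter_config_error")
  }
  rec <- rec[rec$parameter == parameter & rec$scheduled, , drop = FALSE]
  subjects <- study_subjects(study)
  if (is.null(visit_indices)) visit_indices <- seq_len(max(rec$visit_index))
  m <- matrix(NA_real_, length(subjects), length(visit_indices),
              dimnames = list(subjects, visit_indices))
  keep <- rec$visit_index %in% visit_indices & !is.na(rec$value)
  m[cbind(match(rec$subject_id[keep], subjects),
          match(rec$visit_index[keep], visit_indices))] <- rec$value[keep]
  m
}

#' Subjects eligible for a time-series window
#'
#' A subject is eligible for a window of visits when the fraction of
#' missing entries over those visits does not exceed `max_missing_ratio`.
#' A visit with no record counts as missing, and a subject with no
#' observed value at all in the window is never eligible.
#'
#' @param study a `study`.
#' @param parameter measurement parameter name.
#' @param visit_indices non-empty ordered integer vector of visits.
#' @param max_missing_ratio missing-fraction cap in `[0, 1]`.
#' @return Sorted character vector of eligible subject ids.
#' @export
eligible_subjects <- function(study, parameter, visit_indices,
                              max_missing_ratio = 0.30) {
  if (!length(visit_indices)) {
    rlang::abort("visit_indices must be non-empty",
                 class = "sitespotter_config_error")
  }
  m <- param_matrix(study, parameter, visit_indices)
  miss <- rowMeans(is.na(m))
  has_data <- rowSums(!is.na(m)) > 0
  sort(rownames(m)[miss <= max_missing_ratio & has_data])
}

new_ts_group <- function(parameter, visit_indices, values, site_ids) {
  structure(
    list(
      group_id = sprintf("%s/len%d", parameter, length(visit_indices)),
      parameter = parameter,
      visit_indices = as.integer(visit_indices),
      subject_ids = rownames(values),
      values = values,
      site_ids = site_ids[rownames(values)]
    ),
    class = "ts_group"
  )
}

#' @export
print.ts_group <- function(x, ...) {
  cat(sprintf("<ts_group> %s: %d subjects x %d visits\n",
              x$group_id, length(x$subject_ids), length(x$visit_indices)))
  invisible(x)
}

#' Automatic discovery of equal-length time-series groups
#'
#' Candidate windows are schedule prefixes `1..L`. Starting from the
#' longest observed visit index, the longest window whose eligible-subject
#' count reaches `min_group_size` is accepted; a shorter window is then
#' accepted only when its eligible count exceeds the last accepted group's
#' count by at least `improvement_ratio` (relative gain, inclusive). This
#' balances series length against the number of comparable subjects: one
#' long group for subjects who largely finished the trial, and possibly
#' shorter groups that pick up recently enrolled subjects. Groups overlap;
#' a subject may belong to several.
#'
#' @param study a `study`.
#' @param parameter measurement parameter name.
#' @param config a [grouping_config()].
#' @return List of `ts_group` objects, longest first; empty list when no
#'   window reaches `min_group_size`.
#' @export
auto_group <- function(study, parameter, config = grouping_config()) {
  l_max <- max_visit(study, parameter)
  m <- param_matrix(study, parameter, seq_len(l_max))
  miss_cum <- t(apply(is.na(m), 1L, cumsum)) # subject x L missing counts
  if (nrow(m) == 1L) miss_cum <- matrix(miss_cum, nrow = 1L)
  site_ids <- subject_site_map(study)

  groups <- list()
  last_n <- NULL
  for (l in l_max:1) {
    miss_frac <- miss_cum[, l] / l
    eligible <- miss_frac <= config$max_missing_ratio & miss_cum[, l] < l
    n <- sum(eligible)
    accept <-
      if (is.null(last_n)) n >= config$min_group_size
      else n >= last_n * (1 + config$improvement_ratio) - 1e-9
    if (accept) {
      vals <- m[eligible, seq_len(l), drop = FALSE]
      vals <- vals[order(rownames(vals)), , drop = FALSE]
      groups[[length(groups) + 1L]] <- new_ts_group(parameter, seq_len(l),
                                                    vals, site_ids)
      last_n <- n
    }
  }
  groups
}

max_visit <- function(study, parameter) {
  rec <- study$records
  if (!parameter %in% rec$parameter) {
    rlang::abort(sprintf("unknown parameter '%s'", parameter),
                 class = "sitespotter_config_error")
  }
  max(rec$visit_index[rec$parameter == parameter & rec$scheduled])
}

#' Manually defined time-series group
#'
#' Builds the group over exactly the given visits with the same
#' eligibility rule as [auto_group()]; errors when fewer than
#' `min_group_size` subjects qualify. Windows of length one are allowed
#' (some measurements are taken only once, e.g. at screening).
#'
#' @inheritParams eligible_subjects
#' @param config a [grouping_config()].
#' @return A `ts_group`.
#' @export
manual_group <- function(study, parameter, visit_indices,
                         config = grouping_config()) {
  subj <- eligible_subjects(study, parameter, visit_indices,
                            config$max_missing_ratio)
  if (length(subj) < config$min_group_size) {
    rlang::abort(
      sprintf("group too small: %d eligible subject(s), need %d",
              length(subj), config$min_group_size),
      class = "sitespotter_group_too_small",
      count = length(subj)
    )
  }
  m <- param_matrix(study, parameter, visit_indices)
  vals <- m[subj, , drop = FALSE]
  new_ts_group(parameter, visit_indices, vals, subject_site_map(study))
}
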