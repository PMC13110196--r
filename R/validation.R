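#' Validation experiment configuration
#'
#' Settings for the simulation benchmark: how many iterations per cell
#' (default 100), how many anomalous sites per iteration (default 3),
#' which anomaly types, degrees, scoring methods and parameters to cross,
#' the flagging threshold, the grouping settings, and a base seed from
#' which every iteration's seed is derived reproducibly.
#'
#' @param n_iterations iterations per method x type x degree x parameter
#'   cell.
#' @param n_anomalous_sites anomalous sites injected per iteration.
#' @param anomaly_types subset of [feature_names()].
#' @param degrees non-empty numeric grid of anomaly degrees.
#' @param methods subset of `c("ks", "lmm", "average")`.
#' @param parameters parameter names; `NULL` = all parameters of the
#'   study at run time.
#' @param score_threshold flagging threshold (default 1.3).
#' @param grouping a [grouping_config()].
#' @param iqr_multiplier,lmm_draws scoring options, see
#'   [scoring_config()].
#' @param base_seed integer base seed.
#' @return A `validation_config` list.
#' @export
validation_config <- function(n_iterations = 100L, n_anomalous_sites = 3L,
                              anomaly_types = "average",
                              degrees = c(0.1, 0.25, 0.5, 1, 2),
                              methods = "lmm", parameters = NULL,
                              score_threshold = 1.3,
                              grouping = grouping_config(),
                              iqr_multiplier = 1.5, lmm_draws = 1000L,
                              base_seed = 1L) {
  if (n_iterations < 1L || !length(degrees)) {
    rlang::abort("need n_iterations >= 1 and a non-empty degree grid",
                 class = "sitespotter_config_error")
  }
  anomaly_types <- match.arg(anomaly_types, feature_names(),
                             several.ok = TRUE)
  methods <- match.arg(methods, c("ks", "lmm", "average"), several.ok = TRUE)
  structure(
    list(n_iterations = as.integer(n_iterations),
         n_anomalous_sites = as.integer(n_anomalous_sites),
         anomaly_types = anomaly_types, degrees = degrees, methods = methods,
         parameters = parameters, score_threshold = score_threshold,
         grouping = grouping, iqr_multiplier = iqr_multiplier,
         lmm_draws = as.integer(lmm_draws), base_seed = as.integer(base_seed)),
    class = "validation_config"
  )
}

#' One validation iteration: permute, inject, score, flag
#'
#' Reassigns all subjects to sites (washing out any residual site
#' signal), applies the scenario's anomaly, discovers time-series groups,
#' computes the feature paired with the anomaly type, scores sites with
#' the requested method and flags those whose maximum score across groups
#' reaches the threshold (for the average method: flagged in any group).
#' Detection is evaluated on the paired feature only — an average anomaly
#' must be caught by the average feature, an LOF anomaly by the LOF
#' feature, and so on.
#'
#' @param study a cleaned `study`.
#' @param scenario an [anomaly_scenario()]; its `target_sites` are the
#'   ground truth.
#' @param method `"ks"`, `"lmm"` or `"average"`.
#' @param config a [validation_config()].
#' @return List with `flagged`, `truth` and `all_sites` (character
#'   vectors), or with `skipped = TRUE` and a `reason` when no group
#'   reaches the minimum size.
#' @export
run_iteration <- function(study, scenario, method,
                          config = validation_config()) {
  permuted <- reassign_sites(study, mix_seed(scenario$seed, "permute"))
  injected <- inject_anomaly(permuted, scenario)
  groups <- auto_group(injected, scenario$parameter, config$grouping)
  if (!length(groups)) {
    return(list(skipped = TRUE,
                reason = sprintf("no group of >= %d subjects for '%s'",
                                 config$grouping$min_group_size,
                                 scenario$parameter)))
  }
  feature <- scenario$anomaly_type
  fms <- lapply(groups, compute_features, enabled = feature)
  sc <- scoring_config(method = method,
                       score_threshold = config$score_threshold,
                       iqr_multiplier = config$iqr_multiplier,
                       lmm_draws = config$lmm_draws,
                       seed = mix_seed(scenario$seed, "score"))
  tab <- suppressWarnings(score_sites(fms, study_hierarchy(injected), sc))
  list(
    skipped = FALSE,
    flagged = flagged_sites(tab, feature),
    truth = scenario$target_sites,
    all_sites = study_sites(injected)
  )
}

#' Pool iteration results into TPR and FPR
#'
#' True positive rate: flagged truly-anomalous sites over all
#' truly-anomalous sites. False positive rate: flagged compliant sites
#' over all compliant sites. Both are pooled across iterations (sums of
#' counts, not averages of per-iteration rates). Skipped iterations are
#' ignored.
#'
#' @param iteration_results list of [run_iteration()] results.
#' @return Tibble with `tpr`, `fpr`, `n_anomalous`, `n_compliant`,
#'   `n_iterations`.
#' @export
aggregate_tpr_fpr <- function(iteration_results) {
  kept <- Filter(function(r) !isTRUE(r$skipped), iteration_results)
  tp <- fp <- n_anom <- n_comp <- 0L
  for (r in kept) {
    truth <- r$truth
    compliant <- setdiff(r$all_sites, truth)
    tp <- tp + length(intersect(r$flagged, truth))
    fp <- fp + length(intersect(r$flagged, compliant))
    n_anom <- n_anom + length(truth)
    n_comp <- n_comp + length(compliant)
  }
  tibble::tibble(
    tpr = if (n_anom > 0) tp / n_anom else NA_real_,
    fpr = if (n_comp > 0) fp / n_comp else NA_real_,
    n_anomalous = n_anom, n_compliant = n_comp,
    n_iterations = length(kept)
  )
}

#' Run the full anomaly-detection benchmark
#'
#' Full factorial over methods x anomaly types x degrees x parameters.
#' Each cell runs `n_iterations` independent iterations (fresh site
#' permutation, fresh anomalous-site draw, fresh injection randomness),
#' with every iteration's seed derived from `base_seed` and the cell
#' labels, so any scenario can be reproduced in isolation. TPR and FPR
#' are pooled within each cell.
#'
#' @param study a cleaned `study`.
#' @param config a [validation_config()].
#' @return Tibble with one row per cell: `method`, `anomaly_type`,
#'   `degree`, `parameter`, `tpr`, `fpr`, `n_anomalous`, `n_compliant`,
#'   `n_iterations`.
#' @export
run_validation <- function(study, config = validation_config()) {
  params <- config$parameters %||% study_parameters(study)
  cells <- tidyr::expand_grid(
    method = config$methods, anomaly_type = config$anomaly_types,
    degree = config$degrees, parameter = params
  )
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    results <- lapply(seq_len(config$n_iterations), function(it) {
      seed <- mix_seed(config$base_seed, cell$method, cell$anomaly_type,
                       cell$degree, cell$parameter, it)
      scenario <- anomaly_scenario(
        study, anomaly_type = cell$anomaly_type, degree = cell$degree,
        parameter = cell$parameter, n_sites = config$n_anomalous_sites,
        seed = seed
      )
      run_iteration(study, scenario, cell$method, config)
    })
    out[[ci]] <- dplyr::bind_cols(cell, aggregate_tpr_fpr(results))
  }
  dplyr::bind_rows(out)
}
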