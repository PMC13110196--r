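pipeline_sections <- c("steps", "output_dir", "seed", "input", "synth",
                       "grouping", "parameter", "features", "scoring",
                       "inject", "validation", "log_level")

#' Run a declarative analysis pipeline
#'
#' Thin orchestration layer over the package's functions, driven by a
#' config list or YAML file. Recognised top-level keys: `steps` (ordered
#' subset of `synth`, `ingest`, `clean`, `group`, `features`, `score`,
#' `inject`, `validate`), `output_dir`, `seed`, `parameter`, and the
#' per-step sections `input` (path + column map for `ingest`), `synth`,
#' `grouping`, `features` (enabled feature names), `scoring`, `inject`
#' and `validation`. Unknown keys are rejected. Every artifact file
#' starts with a `#` header recording the package version, seed and a
#' hash of the config, so a run can be audited and reproduced.
#'
#' @param config named list or path to a YAML file.
#' @param output_dir overrides the config's output directory.
#' @return Named list of artifact file paths, invisibly.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), pipeline_sections)
  if (length(unknown)) {
    rlang::abort(sprintf("unknown config key(s): %s",
                         paste(unknown, collapse = ", ")),
                 class = "sitespotter_config_error")
  }
  out_dir <- output_dir %||% config$output_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed %||% 1L
  header <- sprintf("# sitespotter %s seed=%s config=%s",
                    as.character(utils::packageVersion("sitespotter")),
                    seed,
                    rlang::hash(config[setdiff(names(config), "output_dir")]))
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    writeLines(header, path)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
    path
  }
  emit_json <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(c(list(`_header` = header), x), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    path
  }

  steps <- config$steps %||% c("synth", "clean", "group", "features", "score")
  study <- NULL
  groups <- NULL
  fms <- NULL
  artifacts <- list()
  gcfg <- do.call(grouping_config, config$grouping %||% list())

  need_study <- function() {
    if (is.null(study)) {
      rlang::abort("this step needs a study; run 'synth' or 'ingest' first",
                   class = "sitespotter_config_error")
    }
  }
  pick_parameter <- function() {
    config$parameter %||% study_parameters(study)[1L]
  }

  for (step in steps) {
    switch(
      step,
      synth = {
        scfg_args <- config$synth %||% list()
        if (!is.null(scfg_args$parameters) &&
            is.character(scfg_args$parameters)) {
          scfg_args$parameters <- synth_parameters(scfg_args$parameters)
        }
        scfg_args$seed <- scfg_args$seed %||% seed
        study <- generate_study(do.call(synth_config, scfg_args))
        artifacts$study <- emit_csv(study$records, "study.csv")
      },
      ingest = {
        inp <- config$input
        if (is.null(inp$path)) {
          rlang::abort("input.path is required for the ingest step",
                       class = "sitespotter_config_error")
        }
        study <- read_study(inp$path, column_map = inp$column_map %||% list(),
                            delim = inp$delim %||% ",")
        artifacts$study <- emit_csv(study$records, "study.csv")
      },
      clean = {
        need_study()
        study <- clean_study(study)
        artifacts$study <- emit_csv(study$records, "study.csv")
      },
      group = {
        need_study()
        groups <- auto_group(study, pick_parameter(), gcfg)
        artifacts$groups <- emit_json(
          lapply(groups, function(g) {
            list(group_id = g$group_id, parameter = g$parameter,
                 visit_indices = g$visit_indices,
                 subject_ids = g$subject_ids)
          }),
          "groups.json"
        )
      },
      features = {
        need_study()
        if (is.null(groups)) {
          groups <- auto_group(study, pick_parameter(), gcfg)
        }
        enabled <- config$features %||% feature_names()
        fms <- lapply(groups, compute_features, enabled = enabled)
        long <- dplyr::bind_rows(lapply(fms, function(fm) {
          tidyr::pivot_longer(
            tibble::as_tibble(fm),
            cols = -c("subject_id", "site_id"),
            names_to = "feature", values_to = "value"
          ) |>
            dplyr::mutate(group_id = attr(fm, "group_id"))
        }))
        artifacts$features <- emit_csv(long, "features.csv")
      },
      score = {
        need_study()
        if (is.null(fms)) {
          rlang::abort("the 'score' step needs 'features' before it",
                       class = "sitespotter_config_error")
        }
        sc_args <- config$scoring %||% list()
        sc_args$seed <- sc_args$seed %||% seed
        tab <- score_sites(fms, study_hierarchy(study),
                           do.call(scoring_config, sc_args))
        artifacts$scores <- emit_csv(tibble::as_tibble(tab), "scores.csv")
      },
      inject = {
        need_study()
        inj <- config$inject %||% list()
        scenario <- anomaly_scenario(
          study,
          anomaly_type = inj$anomaly_type %||% "average",
          degree = inj$degree %||% 1,
          parameter = inj$parameter %||% pick_parameter(),
          target_sites = inj$target_sites,
          n_sites = inj$n_sites %||% 3L,
          seed = inj$seed %||% seed
        )
        study <- inject_anomaly(study, scenario)
        artifacts$injected <- emit_csv(study$records, "injected.csv")
        artifacts$truth <- emit_json(
          list(anomaly_type = scenario$anomaly_type,
               degree = scenario$degree, parameter = scenario$parameter,
               target_sites = scenario$target_sites),
          "truth.json"
        )
      },
      validate = {
        need_study()
        v_args <- config$validation %||% list()
        v_args$grouping <- gcfg
        v_args$base_seed <- v_args$base_seed %||% seed
        res <- run_validation(study, do.call(validation_config, v_args))
        artifacts$validation <- emit_csv(res, "validation.csv")
      },
      rlang::abort(sprintf("unknown step '%s'", step),
                   class = "sitespotter_config_error")
    )
  }
  invisible(artifacts)
}
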