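#' @keywords internal
study_columns <- c(
  "subject_id", "site_id", "country_id", "region_id", "parameter",
  "visit_index", "scheduled", "screen_failure", "value"
)

#' Construct a clinical study object
#'
#' A `study` holds long-format measurement records: one row per subject,
#' measurement parameter and protocol visit, annotated with the
#' site/country/region hierarchy, a visit-schedule flag and a
#' screening-failure flag. Missing country/region columns default to a
#' single synthetic country and region so the site hierarchy is always
#' well formed; missing `scheduled`/`screen_failure` columns default to
#' `TRUE`/`FALSE`.
#'
#' Validation enforces that every subject belongs to exactly one site,
#' every site to one country and every country to one region, that visit
#' indices are positive integers, and that no two scheduled records share
#' a `(subject, parameter, visit)` key. Duplicate keys are an error rather
#' than being averaged away: silent aggregation could mask exactly the
#' anomalies the package is hunting.
#'
#' @param records data frame with at least `subject_id`, `site_id`,
#'   `parameter`, `visit_index`, `value`; optionally `country_id`,
#'   `region_id`, `scheduled`, `screen_failure`.
#' @param validate run the consistency checks (default `TRUE`).
#' @return An object of class `study` wrapping a records tibble.
#' @export
new_study <- function(records, validate = TRUE) {
  records <- tibble::as_tibble(records)
  if (!"country_id" %in% names(records)) records$country_id <- "C1"
  if (!"region_id" %in% names(records)) records$region_id <- "R1"
  if (!"scheduled" %in% names(records)) records$scheduled <- TRUE
  if (!"screen_failure" %in% names(records)) records$screen_failure <- FALSE

  missing_cols <- setdiff(study_columns, names(records))
  if (length(missing_cols)) {
    rlang::abort(
      paste0("records are missing mandatory column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "sitespotter_config_error"
    )
  }
  records <- records[study_columns]
  records$subject_id <- as.character(records$subject_id)
  records$site_id <- as.character(records$site_id)
  records$country_id <- as.character(records$country_id)
  records$region_id <- as.character(records$region_id)
  records$parameter <- as.character(records$parameter)
  records$visit_index <- as.integer(records$visit_index)
  records$scheduled <- as.logical(records$scheduled)
  records$screen_failure <- as.logical(records$screen_failure)
  records$value <- as.double(records$value)

  if (validate) validate_study_records(records)
  structure(list(records = records), class = "study")
}

validate_study_records <- function(records) {
  if (anyNA(records$visit_index) || any(records$visit_index < 1L)) {
    rlang::abort("visit_index must be an integer >= 1 for every record",
                 class = "sitespotter_data_error")
  }
  check_unique_parent <- function(child, parent, what) {
    tab <- unique(data.frame(child = child, parent = parent,
                             stringsAsFactors = FALSE))
    dup <- tab$child[duplicated(tab$child)]
    if (length(dup)) {
      rlang::abort(
        sprintf("%s '%s' is mapped to more than one %s", what[1], dup[1], what[2]),
        class = "sitespotter_data_error"
      )
    }
  }
  check_unique_parent(records$subject_id, records$site_id, c("subject", "site"))
  check_unique_parent(records$site_id, records$country_id, c("site", "country"))
  check_unique_parent(records$country_id, records$region_id, c("country", "region"))

  sched <- records[records$scheduled, , drop = FALSE]
  key <- paste(sched$subject_id, sched$parameter, sched$visit_index, sep = "/")
  if (anyDuplicated(key)) {
    rlang::abort(
      sprintf("duplicate scheduled record for key (subject/parameter/visit) = %s",
              key[duplicated(key)][1]),
      class = "sitespotter_data_error"
    )
  }
  invisible(records)
}

#' @export
print.study <- function(x, ...) {
  r <- x$records
  cat(sprintf(
    "<study> %d records | %d subjects | %d sites | %d countries | %d regions | %d parameters\n",
    nrow(r), dplyr::n_distinct(r$subject_id), dplyr::n_distinct(r$site_id),
    dplyr::n_distinct(r$country_id), dplyr::n_distinct(r$region_id),
    dplyr::n_distinct(r$parameter)
  ))
  invisible(x)
}

#' Study accessors
#'
#' Small helpers returning the parameters, subject ids, site ids and the
#' site -> country -> region hierarchy table of a study.
#'
#' @param study a `study` object.
#' @return `study_parameters()`, `study_subjects()` and `study_sites()`
#'   return sorted character vectors; `study_hierarchy()` a tibble with
#'   columns `site_id`, `country_id`, `region_id`.
#' @export
study_parameters <- function(study) sort(unique(study$records$parameter))

#' @rdname study_parameters
#' @export
study_subjects <- function(study) sort(unique(study$records$subject_id))

#' @rdname study_parameters
#' @export
study_sites <- function(study) sort(unique(study$records$site_id))

#' @rdname study_parameters
#' @export
study_hierarchy <- function(study) {
  h <- dplyr::distinct(study$records[c("site_id", "country_id", "region_id")])
  dplyr::arrange(h, .data$site_id)
}

# named site per subject
subject_site_map <- function(study) {
  m <- dplyr::distinct(study$records[c("subject_id", "site_id")])
  stats::setNames(m$site_id, m$subject_id)
}

#' Read a long-format study from a delimited text file
#'
#' Reads a flat SDTM-like extract (one row per measurement) and maps its
#' columns onto the study record fields via `column_map`, a named list of
#' `field = "file column"` pairs. Mandatory fields are `subject_id`,
#' `site_id`, `parameter`, `visit_index` and `value`; the remaining fields
#' fall back to defaults when their columns are absent. Non-numeric value
#' cells (including `"NA"` and empty strings) become the missing marker
#' `NA`.
#'
#' @param path file path of a delimited table (UTF-8, `.` decimal mark).
#' @param column_map named list overriding the default field -> column
#'   mapping (defaults: each field maps to a column of the same name).
#' @param delim field delimiter, default `","`.
#' @return A validated `study`.
#' @export
read_study <- function(path, column_map = list(), delim = ",") {
  defaults <- stats::setNames(as.list(study_columns), study_columns)
  map <- utils::modifyList(defaults, as.list(column_map))
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, trim_ws = TRUE
  )
  mandatory <- c("subject_id", "site_id", "parameter", "visit_index", "value")
  for (f in mandatory) {
    if (!map[[f]] %in% names(raw)) {
      rlang::abort(
        sprintf("input file has no column '%s' for mandatory field '%s'",
                map[[f]], f),
        class = "sitespotter_config_error"
      )
    }
  }
  pick <- function(f) if (map[[f]] %in% names(raw)) raw[[map[[f]]]] else NULL
  parse_flag <- function(x, default) {
    if (is.null(x)) return(default)
    toupper(trimws(x)) %in% c("TRUE", "T", "1", "YES", "Y")
  }
  visit <- suppressWarnings(as.numeric(pick("visit_index")))
  if (anyNA(visit) || any(visit != round(visit))) {
    rlang::abort("visit_index column must contain integers",
                 class = "sitespotter_data_error")
  }
  records <- tibble::tibble(
    subject_id = pick("subject_id"),
    site_id = pick("site_id"),
    country_id = pick("country_id") %||% "C1",
    region_id = pick("region_id") %||% "R1",
    parameter = pick("parameter"),
    visit_index = as.integer(visit),
    scheduled = parse_flag(pick("scheduled"), TRUE),
    screen_failure = parse_flag(pick("screen_failure"), FALSE),
    value = suppressWarnings(as.numeric(pick("value")))
  )
  new_study(records)
}

#' Write a study back to CSV
#'
#' Writes the canonical record columns as RFC-4180 CSV; `read_study()` on
#' the output round-trips the study.
#'
#' @param study a `study`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  readr::write_csv(study$records, path, progress = FALSE)
  invisible(path)
}

#' Remove unscheduled visits and screening failures
#'
#' Pre-analysis cleaning: drops every record from an unscheduled visit and
#' every record belonging to a subject who failed screening, then prunes
#' the hierarchy to the remaining subjects. Idempotent.
#'
#' @param study a `study`.
#' @return The cleaned `study`.
#' @export
clean_study <- function(study) {
  rec <- study$records
  sf_subjects <- unique(rec$subject_id[rec$screen_failure])
  rec <- rec[rec$scheduled & !(rec$subject_id %in% sf_subjects), , drop = FALSE]
  new_study(rec)
}

#' Randomly reassign subjects to sites
#'
#' Permutes subjects across the existing sites while preserving each
#' site's subject count and the sites' country/region membership. Used to
#' wash out any pre-existing site-level signal before injecting synthetic
#' anomalies.
#'
#' @param study a `study` with at least two sites.
#' @param seed integer seed; the permutation is deterministic per seed.
#' @return A `study` with permuted site assignments.
#' @export
reassign_sites <- function(study, seed) {
  rec <- study$records
  assign <- dplyr::arrange(
    dplyr::distinct(rec[c("subject_id", "site_id")]), .data$subject_id
  )
  if (dplyr::n_distinct(assign$site_id) < 2) {
    rlang::abort("site reassignment needs at least 2 sites",
                 class = "sitespotter_data_error")
  }
  slots <- sort(assign$site_id) # multiset of site labels, counts preserved
  new_assign <- withr::with_seed(
    seed,
    tibble::tibble(subject_id = sample(assign$subject_id), site_id = slots)
  )
  hier <- study_hierarchy(study)
  new_assign <- dplyr::left_join(new_assign, hier, by = "site_id")
  rec <- rec[setdiff(names(rec), c("site_id", "country_id", "region_id"))]
  rec <- dplyr::left_join(rec, new_assign, by = "subject_id")
  new_study(rec[study_columns])
}
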