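#' Synthetic measurement-parameter presets
#'
#' Plausible synthetic location/scale presets for four common clinical
#' measurement types (two laboratory, two vital signs). The numbers are
#' synthetic defaults chosen to be realistic for an adult trial
#' population; they are not estimates from any real study. `round_digits`
#' models the habit of recording some parameters (notably weight and
#' blood pressure) with coarse precision, which depresses the
#' unique-value ratio.
#'
#' @param names optional subset of preset parameter names.
#' @return Tibble with columns `parameter`, `baseline_mean`,
#'   `baseline_sd`, `visit_trend`, `residual_sd`, `round_digits`.
#' @export
synth_parameters <- function(names = NULL) {
  presets <- tibble::tribble(
    ~parameter,                  ~baseline_mean, ~baseline_sd, ~visit_trend, ~residual_sd, ~round_digits,
    "Alanine Aminotransferase",  28,             10,           0.2,          6,            1L,
    "Creatinine",                0.85,           0.15,         0,            0.07,         2L,
    "Systolic Blood Pressure",   126,            12,          -0.3,          8,            0L,
    "Weight",                    78,             14,           0.05,         1.2,          0L
  )
  if (is.null(names)) return(presets)
  missing <- setdiff(names, presets$parameter)
  if (length(missing)) {
    rlang::abort(sprintf("no preset for parameter(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "sitespotter_config_error")
  }
  presets[match(names, presets$parameter), , drop = FALSE]
}

#' Synthetic study configuration
#'
#' Describes the structure of a generated study: the region -> country ->
#' site hierarchy, subjects per site, the protocol visit schedule, the
#' measurement parameters (see [synth_parameters()]) and the nuisance
#' processes that make real trial extracts messy — per-visit missing
#' records, staggered enrollment (subjects observed only on a prefix of
#' the schedule), unscheduled visits and screening failures. By default
#' no site/country/region effect is generated: the validation protocol
#' assumes site-level signal has been washed out, and site scoring should
#' be calibrated on such data. `site_effect_sd` (in units of each
#' parameter's between-subject SD) adds a site-level random shift for
#' power experiments.
#'
#' @param n_regions,n_countries,n_sites hierarchy sizes (countries are
#'   spread round-robin over regions, sites over countries).
#' @param subjects_per_site single integer or length-2 range.
#' @param n_visits number of protocol visits.
#' @param parameters parameter preset tibble.
#' @param missing_rate per-record probability of a skipped visit.
#' @param staggered_fraction fraction of subjects observed only on a
#'   random prefix of the schedule.
#' @param unscheduled_rate per-subject probability of one extra
#'   unscheduled record.
#' @param screen_failure_rate per-subject probability of being a
#'   screening failure (such subjects contribute visit-1 records only).
#' @param site_effect_sd site-level random-intercept SD, as a multiple of
#'   each parameter's `baseline_sd`; default 0.
#' @param seed integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_regions = 2L, n_countries = 4L, n_sites = 20L,
                         subjects_per_site = 15L, n_visits = 8L,
                         parameters = synth_parameters(),
                         missing_rate = 0.05, staggered_fraction = 0.2,
                         unscheduled_rate = 0.05, screen_failure_rate = 0.05,
                         site_effect_sd = 0, seed = 1L) {
  rates <- c(missing_rate, staggered_fraction, unscheduled_rate,
             screen_failure_rate)
  if (any(rates < 0 | rates > 1)) {
    rlang::abort("all rates must lie in [0, 1]",
                 class = "sitespotter_config_error")
  }
  if (n_sites < 2L || any(subjects_per_site < 1L)) {
    rlang::abort("need n_sites >= 2 and subjects_per_site >= 1",
                 class = "sitespotter_config_error")
  }
  structure(
    list(n_regions = as.integer(n_regions),
         n_countries = as.integer(n_countries),
         n_sites = as.integer(n_sites),
         subjects_per_site = as.integer(subjects_per_site),
         n_visits = as.integer(n_visits),
         parameters = tibble::as_tibble(parameters),
         missing_rate = missing_rate,
         staggered_fraction = staggered_fraction,
         unscheduled_rate = unscheduled_rate,
         screen_failure_rate = screen_failure_rate,
         site_effect_sd = site_effect_sd,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a synthetic long-format study
#'
#' Values follow `baseline_subject + visit_trend * visit + noise` with
#' `baseline_subject ~ N(baseline_mean, baseline_sd)` and
#' `noise ~ N(0, residual_sd)`, optionally rounded to `round_digits`
#' decimals. The generator is deterministic per seed and, by default,
#' contains no site, country or region effect, so any site flagged on its
#' output is a false positive by construction.
#'
#' @param config a [synth_config()].
#' @return A `study` (uncleaned: it may contain unscheduled records and
#'   screening failures; run [clean_study()] before analysis).
#' @export
generate_study <- function(config = synth_config()) {
  withr::with_seed(config$seed, {
    regions <- sprintf("R%d", seq_len(config$n_regions))
    countries <- sprintf("C%d", seq_len(config$n_countries))
    country_region <- regions[(seq_len(config$n_countries) - 1L) %%
                                config$n_regions + 1L]
    sites <- sprintf("S%02d", seq_len(config$n_sites))
    site_country <- countries[(seq_len(config$n_sites) - 1L) %%
                                config$n_countries + 1L]

    nsub <- if (length(config$subjects_per_site) == 2L) {
      sample(config$subjects_per_site[1L]:config$subjects_per_site[2L],
             config$n_sites, replace = TRUE)
    } else {
      rep(config$subjects_per_site, config$n_sites)
    }
    n_subjects <- sum(nsub)
    subj <- tibble::tibble(
      subject_id = sprintf("SUBJ%04d", seq_len(n_subjects)),
      site_id = rep(sites, nsub)
    )
    subj$country_id <- site_country[match(subj$site_id, sites)]
    subj$region_id <- country_region[match(subj$country_id, countries)]
    subj$screen_failure <- stats::runif(n_subjects) < config$screen_failure_rate
    staggered <- !subj$screen_failure &
      stats::runif(n_subjects) < config$staggered_fraction
    depth <- sample(seq_len(max(config$n_visits - 1L, 1L)), n_subjects,
                    replace = TRUE)
    subj$max_visit <- ifelse(subj$screen_failure, 1L,
                             ifelse(staggered, depth, config$n_visits))
    subj$unscheduled <- !subj$screen_failure &
      stats::runif(n_subjects) < config$unscheduled_rate

    blocks <- list()
    for (pi in seq_len(nrow(config$parameters))) {
      p <- config$parameters[pi, ]
      site_shift <- stats::rnorm(config$n_sites, 0,
                                 config$site_effect_sd * p$baseline_sd)
      baseline <- stats::rnorm(n_subjects, p$baseline_mean, p$baseline_sd) +
        site_shift[match(subj$site_id, sites)]

      grid <- tidyr::expand_grid(si = seq_len(n_subjects),
                                 visit_index = seq_len(config$n_visits))
      grid <- grid[grid$visit_index <= subj$max_visit[grid$si], , drop = FALSE]
      keep <- stats::runif(nrow(grid)) >= config$missing_rate
      # a subject's first visit is always observed (enrollment measurement)
      keep[grid$visit_index == 1L] <- TRUE
      grid <- grid[keep, , drop = FALSE]
      value <- baseline[grid$si] + p$visit_trend * grid$visit_index +
        stats::rnorm(nrow(grid), 0, p$residual_sd)

      uns_si <- which(subj$unscheduled)
      uns_visit <- sample(config$n_visits, length(uns_si), replace = TRUE)
      uns_value <- baseline[uns_si] + p$visit_trend * uns_visit +
        stats::rnorm(length(uns_si), 0, p$residual_sd)

      if (!is.na(p$round_digits)) {
        value <- round(value, p$round_digits)
        uns_value <- round(uns_value, p$round_digits)
      }
      blocks[[pi]] <- tibble::tibble(
        subject_id = c(subj$subject_id[grid$si], subj$subject_id[uns_si]),
        site_id = c(subj$site_id[grid$si], subj$site_id[uns_si]),
        country_id = c(subj$country_id[grid$si], subj$country_id[uns_si]),
        region_id = c(subj$region_id[grid$si], subj$region_id[uns_si]),
        parameter = p$parameter,
        visit_index = c(grid$visit_index, uns_visit),
        scheduled = rep(c(TRUE, FALSE), c(nrow(grid), length(uns_si))),
        screen_failure = c(subj$screen_failure[grid$si],
                           subj$screen_failure[uns_si]),
        value = c(value, uns_value)
      )
    }
    new_study(dplyr::bind_rows(blocks))
  })
}

#' Deterministic eight-subject grouping fixture
#'
#' A single-parameter toy study illustrating automatic group discovery:
#' subjects S1-S3 have all eight visits, S4-S6 exactly the first four,
#' and S7-S8 too few early visits to qualify for either window (S7 has
#' visits 1-2, S8 visits 2-3). With a minimum group size of 3 and no
#' missing values allowed, [auto_group()] finds exactly two groups: the
#' full-length window with 3 subjects and the first-four-visits window
#' with 6 subjects. Values are arbitrary but fixed; there is no
#' randomness.
#'
#' @return A `study` with 8 subjects, 2 sites and one parameter.
#' @export
grouping_fixture <- function() {
  visits <- list(
    S1 = 1:8, S2 = 1:8, S3 = 1:8,
    S4 = 1:4, S5 = 1:4, S6 = 1:4,
    S7 = 1:2, S8 = 2:3
  )
  rows <- lapply(names(visits), function(s) {
    v <- visits[[s]]
    i <- match(s, names(visits))
    tibble::tibble(
      subject_id = s,
      site_id = if (i <= 4) "SITE_A" else "SITE_B",
      parameter = "Systolic Blood Pressure",
      visit_index = v,
      value = 110 + 2 * i + v
    )
  })
  new_study(dplyr::bind_rows(rows))
}
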