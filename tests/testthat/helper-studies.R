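# Programmatic fixtures shared across test files.

# minimal hand-built study: 2 sites, configurable per-subject visit sets
toy_study <- function(visits_by_subject,
                      sites = NULL,
                      parameter = "Alanine Aminotransferase",
                      values = NULL) {
  subj <- names(visits_by_subject)
  if (is.null(sites)) {
    sites <- rep(c("SA", "SB"), length.out = length(subj))
    names(sites) <- subj
  }
  rows <- lapply(subj, function(s) {
    v <- visits_by_subject[[s]]
    tibble::tibble(
      subject_id = s, site_id = sites[[s]], parameter = parameter,
      visit_index = v,
      value = if (is.null(values)) 10 * match(s, subj) + v else values[[s]]
    )
  })
  new_study(dplyr::bind_rows(rows))
}

# default-condition synthetic study used by the simulation tests:
# 20 sites x 15 subjects x 8 visits, single lab parameter, cleaned
default_validation_study <- function(seed = 20260928) {
  clean_study(generate_study(synth_config(
    parameters = synth_parameters("Alanine Aminotransferase"),
    seed = seed
  )))
}

make_group <- function(values, sites = NULL, parameter = "P") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  }
  if (is.null(sites)) {
    sites <- stats::setNames(rep("SA", nrow(values)), rownames(values))
  }
  sitespotter:::new_ts_group(parameter, seq_len(ncol(values)), values, sites)
}

random_series <- function(n, n_missing = 0) {
  x <- stats::rnorm(n, mean = 50, sd = 10)
  if (n_missing > 0) x[sample(n, n_missing)] <- NA
  x
}
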