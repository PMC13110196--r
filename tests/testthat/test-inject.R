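alt <- "Alanine Aminotransferase"

small_study <- function(seed = 1, n_visits = 8) {
  clean_study(generate_study(synth_config(
    n_sites = 6, subjects_per_site = 8, n_visits = n_visits,
    parameters = synth_parameters(alt),
    missing_rate = 0.05, staggered_fraction = 0, unscheduled_rate = 0,
    screen_failure_rate = 0, seed = seed
  )))
}

scn <- function(study, type, degree, seed = 5, sites = c("S01", "S02")) {
  anomaly_scenario(study, type, degree, alt, target_sites = sites, seed = seed)
}

param_values <- function(study, sites = NULL) {
  rec <- study$records
  keep <- rec$parameter == alt
  if (!is.null(sites)) keep <- keep & rec$site_id %in% sites
  rec[keep, c("subject_id", "site_id", "visit_index", "value")]
}

test_that("scenarios draw target sites reproducibly and validate input", {
  st <- small_study()
  s1 <- anomaly_scenario(st, "average", 1, alt, seed = 9)
  s2 <- anomaly_scenario(st, "average", 1, alt, seed = 9)
  expect_equal(s1$target_sites, s2$target_sites)
  expect_length(s1$target_sites, 3L)
  expect_true(all(s1$target_sites %in% study_sites(st)))
  expect_error(anomaly_scenario(st, "average", -1, alt),
               class = "sitespotter_config_error")
  expect_error(anomaly_scenario(st, "average", 1, "nope"),
               class = "sitespotter_config_error")
  expect_error(anomaly_scenario(st, "average", 1, alt, target_sites = "ZZ"),
               class = "sitespotter_config_error")
})

test_that("every injector is the identity at degree 0 and is seed-stable", {
  st <- small_study()
  for (type in feature_names()) {
    zero <- inject_anomaly(st, scn(st, type, 0))
    expect_equal(zero$records, st$records, info = type)
    one_a <- inject_anomaly(st, scn(st, type, 0.8, seed = 123))
    one_b <- inject_anomaly(st, scn(st, type, 0.8, seed = 123))
    expect_identical(one_a$records, one_b$records, info = type)
  }
})

test_that("injections touch only target sites and preserve structure", {
  st <- small_study(seed = 3)
  for (type in feature_names()) {
    inj <- inject_anomaly(st, scn(st, type, 1.5, seed = 11))
    expect_equal(dim(inj$records), dim(st$records))
    expect_equal(is.na(inj$records$value), is.na(st$records$value))
    expect_equal(inj$records$visit_index, st$records$visit_index)
    off_target <- st$records$site_id %in% c("S03", "S04", "S05", "S06")
    expect_identical(inj$records$value[off_target],
                     st$records$value[off_target], info = type)
  }
})

test_that("the mean-shift injection scales site means linearly", {
  st <- small_study(seed = 4)
  pre <- param_values(st, "S01")
  inj <- inject_average(st, scn(st, "average", 0.5, sites = "S01"))
  post <- param_values(inj, "S01")
  expect_equal(mean(post$value), 1.5 * mean(pre$value), tolerance = 1e-10)
  # constant-site example: all 10s at degree 1 become 20
  rec <- tibble::tibble(
    subject_id = rep(c("A", "B", "C", "D"), each = 2),
    site_id = rep(c("X", "Y"), each = 4), parameter = "P",
    visit_index = rep(1:2, 4), value = 10
  )
  tiny <- new_study(rec)
  s <- anomaly_scenario(tiny, "average", 1, "P", target_sites = "X")
  expect_equal(inject_average(tiny, s)$records$value, c(rep(20, 4), rep(10, 4)))
})

test_that("the spread injection keeps the mean but inflates per-subject SD", {
  st <- small_study(seed = 6)
  pre <- param_values(st, "S01")
  inj <- inject_sd(st, scn(st, "sd", 1, sites = "S01", seed = 21))
  post <- param_values(inj, "S01")
  se <- sd(post$value) / sqrt(nrow(post))
  expect_lt(abs(mean(post$value) - mean(pre$value)), 3 * se)
  pre_sd <- tapply(pre$value, pre$subject_id, sd)
  post_sd <- tapply(post$value, post$subject_id, sd)
  expect_gte(mean(post_sd > pre_sd), 0.95)
})

test_that("the outlier injection changes exactly one visit per subject", {
  st <- small_study(seed = 8)
  inj <- inject_range(st, scn(st, "range", 1, seed = 31))
  pre <- param_values(st, c("S01", "S02"))
  post <- param_values(inj, c("S01", "S02"))
  changed <- tapply(pre$value != post$value, pre$subject_id, sum)
  expect_true(all(changed == 1))
  # per-subject range is non-decreasing in degree
  rng_at <- function(d) {
    x <- param_values(inject_range(st, scn(st, "range", d, seed = 31)),
                      c("S01", "S02"))
    tapply(x$value, x$subject_id, function(v) max(v) - min(v))
  }
  r0 <- rng_at(0); r05 <- rng_at(0.5); r1 <- rng_at(1); r2 <- rng_at(2)
  expect_true(all(r05 >= r0 - 1e-9))
  expect_true(all(r1 >= r05 - 1e-9))
  expect_true(all(r2 >= r1 - 1e-9))
})

test_that("the duplication injection replaces the stated share of later values", {
  st <- small_study(seed = 9)
  # full replacement: every target series becomes constant at first value
  inj1 <- inject_unique(st, scn(st, "unique_value_ratio", 1, seed = 41))
  post <- param_values(inj1, c("S01", "S02"))
  n_unique <- tapply(post$value, post$subject_id, function(v) length(unique(v)))
  expect_true(all(n_unique == 1))
  # complete 8-visit series at degree 0.5: round-half-up(0.5 * 7) = 4 replaced
  complete <- small_study(seed = 10)
  pre <- param_values(complete, c("S01", "S02"))
  full <- names(which(table(pre$subject_id) == 8))
  inj05 <- inject_unique(complete, scn(complete, "unique_value_ratio", 0.5,
                                       seed = 43))
  post05 <- param_values(inj05, c("S01", "S02"))
  for (sj in full) {
    a <- pre$value[pre$subject_id == sj][order(pre$visit_index[pre$subject_id == sj])]
    b <- post05$value[post05$subject_id == sj][order(post05$visit_index[post05$subject_id == sj])]
    expect_equal(sum(a != b & b == a[1]) + sum(a != b & b != a[1]), sum(a != b))
    expect_equal(sum(a != b), 4L, info = sj)
    expect_true(all(b[b != a] == a[1]))
  }
})

test_that("the trending injection adds the original predecessor", {
  rec <- tibble::tibble(
    subject_id = rep(c("A", "B"), each = 2), site_id = rep(c("X", "Y"), each = 2),
    parameter = "P", visit_index = rep(1:2, 2), value = c(2, 4, 2, 4)
  )
  tiny <- new_study(rec)
  s <- anomaly_scenario(tiny, "autocorrelation", 0.5, "P", target_sites = "X")
  got <- inject_autocorrelation(tiny, s)$records$value
  expect_equal(got, c(2, 5, 2, 4))
  # no cascading: x'_3 uses original x_2
  rec3 <- tibble::tibble(
    subject_id = c("A", "A", "A", "B"), site_id = c("X", "X", "X", "Y"),
    parameter = "P", visit_index = c(1:3, 1), value = c(1, 2, 4, 9)
  )
  s3 <- anomaly_scenario(new_study(rec3), "autocorrelation", 1, "P",
                         target_sites = "X")
  expect_equal(inject_autocorrelation(new_study(rec3), s3)$records$value,
               c(1, 3, 6, 9))
  # a missing predecessor leaves the value unchanged
  rec_gap <- tibble::tibble(
    subject_id = c("A", "A", "B"), site_id = c("X", "X", "Y"),
    parameter = "P", visit_index = c(1, 3, 1), value = c(1, 4, 9)
  )
  sg <- anomaly_scenario(new_study(rec_gap), "autocorrelation", 1, "P",
                         target_sites = "X")
  expect_equal(inject_autocorrelation(new_study(rec_gap), sg)$records$value,
               c(1, 4, 9))
})

test_that("the trending injection raises lag-1 autocorrelation", {
  wins <- 0L
  n_rep <- 30L
  for (i in seq_len(n_rep)) {
    st <- small_study(seed = 500 + i)
    inj <- inject_autocorrelation(st, scn(st, "autocorrelation", 1,
                                          seed = 600 + i, sites = "S01"))
    pre <- param_values(st, "S01")
    post <- param_values(inj, "S01")
    ac <- function(tab) {
      mean(vapply(split(tab, tab$subject_id), function(d) {
        v <- d$value[order(d$visit_index)]
        a <- ts_autocorrelation(v)
        if (is.na(a)) 0 else a
      }, numeric(1)))
    }
    if (ac(post) > ac(pre)) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.9)
})

test_that("the distributional injection hits the stated share of subjects", {
  st <- small_study(seed = 12)
  pre <- param_values(st, c("S01", "S02"))
  inj1 <- inject_lof(st, scn(st, "lof", 1, seed = 51))
  post1 <- param_values(inj1, c("S01", "S02"))
  touched <- tapply(pre$value != post1$value, pre$subject_id, any)
  expect_true(all(touched))
  # degree 0.5 -> half of the 16 target subjects transformed
  inj05 <- inject_lof(st, scn(st, "lof", 0.5, seed = 51))
  post05 <- param_values(inj05, c("S01", "S02"))
  touched05 <- tapply(pre$value != post05$value, pre$subject_id, any)
  expect_equal(sum(touched05), 8L)
  # per-subject means preserved within 20%
  pre_mean <- tapply(pre$value, pre$subject_id, mean)
  post_mean <- tapply(post1$value, post1$subject_id, mean)
  expect_true(all(abs(post_mean - pre_mean) <= 0.2 * abs(pre_mean)))
})

test_that("random scenarios keep all structural invariants", {
  st <- small_study(seed = 14)
  types <- feature_names()
  for (i in 1:40) {
    seed <- 900 + i
    type <- types[(i - 1) %% 6 + 1]
    degree <- c(0, 0.25, 0.5, 1, 2)[(i - 1) %% 5 + 1]
    s <- anomaly_scenario(st, type, degree, alt, n_sites = 2, seed = seed)
    inj <- inject_anomaly(st, s)
    expect_equal(nrow(inj$records), nrow(st$records))
    expect_equal(is.na(inj$records$value), is.na(st$records$value))
    off <- !st$records$site_id %in% s$target_sites
    expect_identical(inj$records$value[off], st$records$value[off])
    if (degree == 0) expect_equal(inj$records, st$records)
  }
})
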