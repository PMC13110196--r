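test_that("ks_site_pvalue handles identity, disjoint and empty samples", {
  same <- ks_site_pvalue(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  x <- 1:8
  y <- 101:108
  got <- ks_site_pvalue(x, y)
  expect_equal(got$statistic, 1)
  expect_equal(got$p_value, oracle_ks_exact_p(x, y), tolerance = 1e-10)

  empty <- ks_site_pvalue(numeric(0), c(1, 2))
  expect_true(is.na(empty$statistic) && is.na(empty$p_value))
  expect_true(is.na(ks_site_pvalue(c(NA_real_, NA_real_), c(1, 2))$p_value))
})

test_that("raw K-S p-values are calibrated under the null", {
  withr::with_seed(2026, {
    hits <- 0L
    n_rep <- 500L
    for (i in seq_len(n_rep)) {
      p <- ks_site_pvalue(rnorm(20), rnorm(200))$p_value
      if (p < 0.05) hits <- hits + 1L
    }
  })
  expect_gt(hits / n_rep, 0.025)
  expect_lt(hits / n_rep, 0.075)
})

test_that("by_adjust matches the hand-rolled step-up oracle", {
  expect_equal(by_adjust(0.04), 0.04)
  expect_equal(by_adjust(c(0.01, 0.02, 0.03)), rep(0.055, 3),
               tolerance = 1e-12)
  withr::with_seed(5, {
    for (i in 1:50) {
      p <- runif(sample(2:40, 1))
      adj <- by_adjust(p)
      expect_equal(adj, oracle_by(p), tolerance = 1e-12)
      expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
      # monotone: ordering of p preserved in the adjusted values
      expect_true(all(diff(adj[order(p)]) > -1e-15))
    }
  })
  # NAs pass through without joining the family
  p <- c(0.01, NA, 0.02, 0.03)
  adj <- by_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[-2], oracle_by(p[-2]), tolerance = 1e-12)
  expect_error(by_adjust(c(0.5, 1.2)), class = "sitespotter_config_error")
})

test_that("anomaly_score is -log10 with a floor at 1e-300", {
  expect_equal(anomaly_score(0.05), 1.30103, tolerance = 1e-5)
  expect_equal(anomaly_score(1), 0)
  expect_equal(anomaly_score(0.001), 3)
  expect_equal(anomaly_score(0), 300)
  expect_true(is.na(anomaly_score(NA_real_)))
})

test_that("average_site_flags applies strict IQR fences", {
  one_each <- function(means) {
    average_site_flags(unname(means), names(means))
  }
  means <- stats::setNames(c(rep(1, 9), 50), sprintf("S%02d", 1:10))
  flags <- one_each(means)
  expect_equal(names(flags)[flags], "S10")

  expect_false(any(one_each(stats::setNames(rep(2, 6), paste0("S", 1:6)))))

  # a site exactly at Q3 + 1.5*IQR is not an outlier (strict fences):
  # for site means (1,2,3,4,7), Q1 = 2, Q3 = 4, upper fence = 7
  means <- stats::setNames(c(1, 2, 3, 4, 7), paste0("S", 1:5))
  expect_false(any(one_each(means)))
  expect_true(one_each(stats::setNames(c(1, 2, 3, 4, 7.001),
                                       paste0("S", 1:5)))[["S5"]])

  expect_warning(f <- average_site_flags(c(1, 2, 3), c("A", "B", "C")),
                 "fewer than 4")
  expect_false(any(f))
})

make_hier <- function(n_sites, n_countries = 1, n_regions = 1) {
  tibble::tibble(
    site_id = sprintf("S%02d", seq_len(n_sites)),
    country_id = sprintf("C%d", (seq_len(n_sites) - 1) %% n_countries + 1),
    region_id = sprintf("R%d", (seq_len(n_sites) - 1) %% n_regions + 1)
  )
}

test_that("lmm p-values recover a strongly shifted site", {
  n_sites <- 20
  n_per <- 10
  hier <- make_hier(n_sites, n_countries = 4, n_regions = 2)
  withr::with_seed(31, {
    sites <- rep(hier$site_id, each = n_per)
    y <- rnorm(n_sites * n_per, sd = 1)
    y[sites == "S07"] <- y[sites == "S07"] + 10 # 10 residual SDs
  })
  res <- lmm_site_pvalues(y, sites, hier, n_draws = 1000, seed = 4)
  p <- stats::setNames(res$site$p_value, res$site$entity_id)
  expect_equal(names(which.min(p)), "S07")
  expect_lt(p[["S07"]], 0.001)
  # determinism
  res2 <- lmm_site_pvalues(y, sites, hier, n_draws = 1000, seed = 4)
  expect_equal(res$site, res2$site)
})

test_that("lmm is roughly calibrated under a pure-noise null", {
  hier <- make_hier(20, n_countries = 4, n_regions = 2)
  n_sig <- 0L
  n_tot <- 0L
  for (rep in 1:25) {
    withr::with_seed(1000 + rep, {
      sites <- rep(hier$site_id, each = 10)
      y <- rnorm(200)
    })
    res <- suppressWarnings(
      lmm_site_pvalues(y, sites, hier, n_draws = 400, seed = rep)
    )
    n_sig <- n_sig + sum(res$site$p_value < 0.05, na.rm = TRUE)
    n_tot <- n_tot + sum(!is.na(res$site$p_value))
  }
  expect_lte(n_sig / n_tot, 0.10)
})

test_that("single-country single-region hierarchies yield p = 1 there", {
  hier <- make_hier(6)
  withr::with_seed(9, {
    sites <- rep(hier$site_id, each = 8)
    y <- rnorm(48)
  })
  res <- suppressWarnings(lmm_site_pvalues(y, sites, hier, n_draws = 200,
                                           seed = 2))
  expect_true(all(res$country$p_value == 1))
  expect_true(all(res$region$p_value == 1))
})

test_that("score_sites flags on the max score across groups", {
  # two groups; one site far off in group 2 only
  withr::with_seed(77, {
    v1 <- matrix(rnorm(40 * 4, 50, 5), 40, 4)
    v2 <- matrix(rnorm(40 * 2, 50, 5), 40, 2)
  })
  sites <- stats::setNames(rep(sprintf("S%02d", 1:8), each = 5),
                           sprintf("S%03d", 1:40))
  v2[1:5, ] <- v2[1:5, ] + 200 # site S01 shifted in the short group
  rownames(v1) <- rownames(v2) <- names(sites)
  g1 <- make_group(v1, sites = sites)
  g2 <- make_group(v2, sites = sites)
  hier <- make_hier(8)
  fms <- lapply(list(g1, g2), compute_features, enabled = "average")
  tab <- score_sites(fms, hier, scoring_config("ks", seed = 1))
  expect_s3_class(tab, "score_table")
  expect_equal(flagged_sites(tab, "average"), "S01")
  # scores satisfy score = -log10(adjusted_p); adjusted >= raw
  ok <- !is.na(tab$adjusted_p)
  expect_equal(tab$score[ok], -log10(tab$adjusted_p[ok]), tolerance = 1e-12)
  expect_true(all(tab$adjusted_p[ok] >= tab$raw_p[ok] - 1e-15))
  # the family-wide BY adjustment equals an independent oracle
  raw <- tab$raw_p[!is.na(tab$raw_p)]
  expect_equal(tab$adjusted_p[!is.na(tab$raw_p)], oracle_by(raw),
               tolerance = 1e-12)
})

test_that("all-null p-values give zero scores and no flags", {
  v <- matrix(5, 12, 3) # identical everywhere -> every K-S p is 1
  sites <- stats::setNames(rep(sprintf("S%02d", 1:4), each = 3),
                           sprintf("P%03d", 1:12))
  rownames(v) <- names(sites)
  g <- make_group(v, sites = sites)
  tab <- score_sites(list(compute_features(g, enabled = "average")),
                     make_hier(4), scoring_config("ks"))
  expect_true(all(tab$score == 0))
  expect_false(any(tab$flagged))
})

test_that("the average method flags per group without p-values", {
  withr::with_seed(3, {
    v <- matrix(rnorm(50 * 3, 10, 1), 50, 3)
  })
  sites <- stats::setNames(rep(sprintf("S%02d", 1:10), each = 5),
                           sprintf("P%03d", 1:50))
  v[sites == "S04", ] <- v[sites == "S04", ] + 100
  rownames(v) <- names(sites)
  g <- make_group(v, sites = sites)
  tab <- score_sites(list(compute_features(g, enabled = "average")),
                     make_hier(10), scoring_config("average"))
  expect_true(all(is.na(tab$raw_p)))
  expect_true(all(is.na(tab$score)))
  # the shifted site is flagged; narrow fences may add chance flags,
  # which is exactly the method's known false-positive weakness
  expect_true("S04" %in% flagged_sites(tab, "average"))
})
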