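#' Scoring configuration
#'
#' Options for site-level anomaly scoring. `method` selects one of the
#' three procedures: `"ks"` (two-sample Kolmogorov-Smirnov test of each
#' site's feature values against the pooled values of all other sites),
#' `"lmm"` (nested-random-intercept mixed model with simulated random
#' effects) or `"average"` (IQR fence rule on site mean feature values,
#' which yields flags but no p-values). Sites are flagged when their
#' maximum score over time-series groups reaches `score_threshold`;
#' the default 1.3 corresponds to an adjusted p-value of about 0.05.
#'
#' @param method `"ks"`, `"lmm"` or `"average"`.
#' @param score_threshold positive score cut-off (default 1.3).
#' @param iqr_multiplier fence width for the average method (default 1.5).
#' @param lmm_draws number of simulated random-effect draws per entity
#'   (default 1000).
#' @param seed integer seed for the random-effect draws.
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(method = c("ks", "lmm", "average"),
                           score_threshold = 1.3, iqr_multiplier = 1.5,
                           lmm_draws = 1000L, seed = 1L) {
  method <- rlang::arg_match(method)
  if (score_threshold <= 0 || iqr_multiplier <= 0) {
    rlang::abort("score_threshold and iqr_multiplier must be > 0",
                 class = "sitespotter_config_error")
  }
  structure(
    list(method = method, score_threshold = score_threshold,
         iqr_multiplier = iqr_multiplier, lmm_draws = as.integer(lmm_draws),
         seed = as.integer(seed)),
    class = "scoring_config"
  )
}

#' Kolmogorov-Smirnov comparison of one site against the rest
#'
#' Two-sided two-sample K-S test of a site's feature values against the
#' pooled feature values of all other sites: the D statistic is the
#' maximum vertical gap between the two empirical CDFs. Small samples
#' without ties use the exact null distribution (as in
#' [stats::ks.test()]); otherwise the asymptotic one. Sites of any size
#' are testable, down to a single subject.
#'
#' @param site_values numeric feature values at the site.
#' @param other_values pooled feature values of all other sites.
#' @return List with `statistic` (D in `[0, 1]`) and `p_value`; both `NA`
#'   when either sample is empty after dropping undefined values.
#' @export
ks_site_pvalue <- function(site_values, other_values) {
  x <- site_values[!is.na(site_values)]
  y <- other_values[!is.na(other_values)]
  if (!length(x) || !length(y)) {
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  kt <- suppressWarnings(stats::ks.test(x, y, alternative = "two.sided"))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Mixed-effects site/country/region p-values for one feature
#'
#' Fits an intercept-only linear mixed model of the feature values with
#' nested random intercepts (site within country within region; levels
#' with a single group are dropped), then simulates `n_draws` realisations
#' of each entity's random effect from its conditional (posterior) normal
#' distribution. The median `m` and standard deviation `s` of the draws
#' give the two-sided p-value `2 * pnorm(-|m - c| / s)` for the entity's
#' deviation, where the centre `c` is the median of the entity medians at
#' that level. Recentring on a robust cross-entity location instead of
#' raw zero matters when several sites are grossly anomalous: they drag
#' the fitted grand intercept with them, and relative to that biased
#' intercept every compliant site's random effect would "deviate from
#' zero" and be flagged; under clean data the centre is essentially zero
#' and the recentring is a no-op. Entities whose level was dropped (or a
#' degenerate fit) get p = 1; sites with no defined feature value get
#' `NA`.
#'
#' @param values numeric feature values, one per subject.
#' @param sites character site id per subject.
#' @param hierarchy tibble with `site_id`, `country_id`, `region_id`.
#' @param n_draws number of simulated random-effect draws.
#' @param seed integer seed; draws are deterministic per seed.
#' @return List of three tibbles (`site`, `country`, `region`), each with
#'   columns `entity_id` and `p_value`.
#' @export
lmm_site_pvalues <- function(values, sites, hierarchy, n_draws = 1000L,
                             seed = 1L) {
  hier <- dplyr::arrange(tibble::as_tibble(hierarchy), .data$site_id)
  dat <- tibble::tibble(y = values, site_id = sites)
  dat <- dplyr::left_join(dat, hier, by = "site_id")
  dat <- dat[!is.na(dat$y), , drop = FALSE]

  ones <- function(ids) tibble::tibble(entity_id = ids, p_value = 1)
  nas <- function(ids) tibble::tibble(entity_id = ids, p_value = NA_real_)
  all_sites <- hier$site_id
  all_countries <- sort(unique(hier$country_id))
  all_regions <- sort(unique(hier$region_id))
  degenerate <- function() {
    list(site = ones(all_sites), country = ones(all_countries),
         region = ones(all_regions))
  }
  if (nrow(dat) == 0L) { # feature undefined everywhere: untestable
    return(list(site = nas(all_sites), country = nas(all_countries),
                region = nas(all_regions)))
  }
  if (nrow(dat) < 3L || dplyr::n_distinct(dat$site_id) < 2L ||
      stats::sd(dat$y) == 0) {
    rlang::warn("mixed model degenerate: too little variation; all p = 1")
    return(degenerate())
  }

  terms <- "(1 | site_id)"
  if (dplyr::n_distinct(dat$country_id) > 1L) {
    terms <- c("(1 | country_id)", terms)
  }
  if (dplyr::n_distinct(dat$region_id) > 1L) {
    terms <- c("(1 | region_id)", terms)
  }
  fml <- stats::as.formula(paste("y ~ 1 +", paste(terms, collapse = " + ")))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(lme4::lmer(
      fml, data = dat, REML = TRUE,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore")
    ))),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    rlang::warn("mixed model failed to fit; all p = 1")
    return(degenerate())
  }

  re <- lme4::ranef(fit, condVar = TRUE)
  entity_p <- function(fac, universe) {
    if (!fac %in% names(re)) return(ones(universe))
    tab <- re[[fac]]
    mu <- tab[, 1L]
    sdv <- sqrt(pmax(attr(tab, "postVar")[1L, 1L, ], 0))
    draws <- withr::with_seed(mix_seed(seed, fac), {
      matrix(stats::rnorm(length(mu) * n_draws, mean = mu, sd = sdv),
             nrow = length(mu))
    })
    med <- apply(draws, 1L, stats::median)
    s <- apply(draws, 1L, stats::sd)
    centre <- stats::median(med) # robust to a few contaminated entities
    p <- ifelse(s <= 0, 1, 2 * stats::pnorm(-abs(med - centre) / s))
    res <- tibble::tibble(entity_id = rownames(tab), p_value = p)
    missing_ids <- setdiff(universe, res$entity_id)
    dplyr::arrange(dplyr::bind_rows(res, nas(missing_ids)), .data$entity_id)
  }
  list(
    site = entity_p("site_id", all_sites),
    country = entity_p("country_id", all_countries),
    region = entity_p("region_id", all_regions)
  )
}

#' IQR outlier flags on site mean feature values
#'
#' The baseline method: each site is summarised by the mean feature value
#' of its subjects, and sites strictly below `Q1 - m * IQR` or strictly
#' above `Q3 + m * IQR` of the site means are flagged (boundary values are
#' not outliers). No p-value is produced. Needs at least four sites with a
#' defined mean; otherwise all flags are `FALSE` with a warning.
#'
#' @param values numeric feature values, one per subject.
#' @param sites character site id per subject.
#' @param iqr_multiplier fence width `m` (default 1.5).
#' @return Named logical vector, one flag per site.
#' @export
average_site_flags <- function(values, sites, iqr_multiplier = 1.5) {
  means <- tapply(values, sites, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  flags <- stats::setNames(rep(FALSE, length(means)), names(means))
  usable <- !is.na(means)
  if (sum(usable) < 4L) {
    rlang::warn("fewer than 4 sites with a defined mean; no site flagged")
    return(flags)
  }
  q <- stats::quantile(means[usable], c(0.25, 0.75), names = FALSE)
  iqr <- q[2L] - q[1L]
  lo <- q[1L] - iqr_multiplier * iqr
  hi <- q[2L] + iqr_multiplier * iqr
  flags[usable] <- means[usable] < lo | means[usable] > hi
  flags
}

#' Benjamini-Yekutieli adjustment
#'
#' Step-up FDR adjustment valid under arbitrary dependence (the same
#' subjects' data are reused across the many site-versus-rest
#' comparisons): adjusted p-values are `p * m * c(m) / rank` with the
#' harmonic inflation factor `c(m) = sum(1/j)`, cumulative-minimised from
#' the largest rank and capped at 1. `NA` entries pass through and do not
#' count towards the family size.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values in the original order.
#' @export
by_adjust <- function(pvalues) {
  stopifnot_probability(pvalues, "pvalues")
  out <- pvalues
  ok <- !is.na(pvalues)
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BY")
  out
}

#' Anomaly score of an adjusted p-value
#'
#' `-log10` of the multiplicity-adjusted p-value; the flagging threshold
#' of 1.3 corresponds to an adjusted p of about 0.05. Zeros are floored at
#' `1e-300` before taking the logarithm.
#'
#' @param adjusted_p adjusted p-value(s) in `[0, 1]`.
#' @return Non-negative score(s); `NA` passes through.
#' @export
anomaly_score <- function(adjusted_p) {
  stopifnot_probability(adjusted_p, "adjusted_p")
  -log10(pmax(adjusted_p, 1e-300)) + 0 # + 0 normalises -log10(1) = -0
}

#' Score sites across features and time-series groups
#'
#' Runs the configured method for every site x feature x group cell. For
#' the `ks` and `lmm` methods all raw p-values of the run form one family
#' for the Benjamini-Yekutieli correction; scores are `-log10` of the
#' adjusted p-values and a site x feature is flagged when its maximum
#' score across groups reaches `config$score_threshold`. The `average`
#' method produces no p-values; a site x feature is flagged when the IQR
#' rule flags it in any group. For `lmm`, country- and region-level
#' p-values are attached as the `"entity_pvalues"` attribute (reported,
#' but never used for site flagging).
#'
#' @param features_by_group list of `feature_matrix` objects, one per
#'   time-series group (see [compute_features()]).
#' @param hierarchy tibble with `site_id`, `country_id`, `region_id`.
#' @param config a [scoring_config()].
#' @return A `score_table` tibble with columns `site_id`, `feature`,
#'   `group_id`, `method`, `raw_p`, `adjusted_p`, `score`, `flagged`.
#' @export
score_sites <- function(features_by_group, hierarchy,
                        config = scoring_config()) {
  if (!length(features_by_group)) {
    rlang::abort("need at least one feature matrix",
                 class = "sitespotter_config_error")
  }
  hier <- dplyr::arrange(tibble::as_tibble(hierarchy), .data$site_id)
  all_sites <- hier$site_id
  rows <- list()
  entity_tabs <- list()

  for (fm in features_by_group) {
    gid <- attr(fm, "group_id")
    feats <- intersect(feature_names(), names(fm))
    for (f in feats) {
      v <- fm[[f]]
      s <- fm$site_id
      if (config$method == "ks") {
        raw <- unname(vapply(all_sites, function(st) {
          ks_site_pvalue(v[s == st], v[s != st])$p_value
        }, numeric(1)))
      } else if (config$method == "lmm") {
        res <- lmm_site_pvalues(v, s, hier, n_draws = config$lmm_draws,
                                seed = mix_seed(config$seed, gid, f))
        raw <- res$site$p_value[match(all_sites, res$site$entity_id)]
        entity_tabs[[paste(gid, f, sep = "|")]] <-
          dplyr::bind_rows(
            dplyr::mutate(res$country, level = "country", group_id = gid,
                          feature = f),
            dplyr::mutate(res$region, level = "region", group_id = gid,
                          feature = f)
          )
      } else { # average
        fl <- average_site_flags(v, s, config$iqr_multiplier)
        raw <- rep(NA_real_, length(all_sites))
      }
      rows[[paste(gid, f, sep = "|")]] <- tibble::tibble(
        site_id = all_sites, feature = f, group_id = gid,
        method = config$method, raw_p = raw,
        group_flag = if (config$method == "average") {
          unname(fl[match(all_sites, names(fl))])
        } else {
          NA
        }
      )
    }
  }
  tab <- dplyr::bind_rows(rows)
  if (config$method == "average") {
    tab$adjusted_p <- NA_real_
    tab$score <- NA_real_
    tab$group_flag[is.na(tab$group_flag)] <- FALSE
    tab <- dplyr::mutate(
      dplyr::group_by(tab, .data$site_id, .data$feature),
      flagged = any(.data$group_flag)
    )
    tab <- dplyr::ungroup(tab)
    tab$group_flag <- NULL
  } else {
    tab$adjusted_p <- by_adjust(tab$raw_p)
    tab$score <- anomaly_score(tab$adjusted_p)
    tab$group_flag <- NULL
    tab <- dplyr::mutate(
      dplyr::group_by(tab, .data$site_id, .data$feature),
      flagged = any(!is.na(.data$score) &
                      .data$score >= config$score_threshold)
    )
    tab <- dplyr::ungroup(tab)
  }
  tab <- tab[c("site_id", "feature", "group_id", "method", "raw_p",
               "adjusted_p", "score", "flagged")]
  if (length(entity_tabs)) {
    attr(tab, "entity_pvalues") <- dplyr::bind_rows(entity_tabs)
  }
  class(tab) <- c("score_table", class(tab))
  tab
}

#' Sites flagged for a feature
#'
#' @param score_table result of [score_sites()].
#' @param feature feature name to filter on; default all features.
#' @return Sorted character vector of flagged site ids.
#' @export
flagged_sites <- function(score_table, feature = NULL) {
  tab <- score_table
  if (!is.null(feature)) tab <- tab[tab$feature == feature, , drop = FALSE]
  sort(unique(tab$site_id[tab$flagged]))
}
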