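---
title: "Detecting anomalous sites in clinical trial time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting anomalous sites in clinical trial time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Most clinical trial data are repeated measurements of the same subjects
over protocol visits. Systematic errors introduced at an investigation
site — protocol misinterpretation, miscalibrated devices, unit mix-ups,
copied or fabricated values — affect many subjects at that site and
should be statistically visible against the rest of the study, provided
like is compared with like. Two things make the comparison treacherous
in an ongoing trial: subjects enrol at different times (series have
different lengths) and visits are skipped (series have holes). Naively
pooling aggregates across series of different lengths confounds
protocol-driven differences with data-quality signals.

`sitespotter` addresses this by only ever comparing *time series
composed of the same visits*, then summarising each series into scalar
features, and finally scoring each site's feature distribution against
the rest of the study with multiplicity-corrected tests.

## Equal-length time-series groups

For each measurement parameter, `auto_group()` searches candidate
windows that are prefixes `1..L` of the visit schedule, starting from
the longest observed visit. A subject is eligible for a window when its
fraction of missing entries there is at most `max_missing_ratio`
(default 0.30; a visit without a record counts as missing, and a subject
with no observed value in the window is never eligible). The longest
window with at least `min_group_size` eligible subjects (default 25)
is accepted; a shorter window is accepted only when it increases the
eligible count by at least `improvement_ratio` (default 0.20, i.e. 20%,
inclusive). Groups therefore overlap — a subject who completed the trial
belongs to the long group and to every accepted shorter one. Windows of
length one are allowed because some measurements are taken only once
(e.g. at screening); features that need at least two observations are
simply undefined there.

Design choices worth stating explicitly: only prefix windows are
searched (arbitrary sub-windows are not); the 20% rule is a relative
gain and inclusive at the boundary; when two windows tie on eligible
count the longer one is kept (a zero gain never justifies a shorter
window); and the search decrements the window length one visit at a
time.

```{r}
library(sitespotter)
study <- clean_study(generate_study(synth_config(seed = 1)))
auto_group(study, "Alanine Aminotransferase")
```

## The six features

Each subject's series in a group is summarised by up to six scalars,
each sensitive to a different real-world failure mode:

| feature              | catches                                           |
|----------------------|---------------------------------------------------|
| `average`            | systematic shifts (calibration bias)              |
| `sd`                 | implausible fluctuation                           |
| `range`              | magnitude/unit errors                             |
| `unique_value_ratio` | duplication and coarse rounding                   |
| `autocorrelation`    | artificial trending (constants added to previous) |
| `lof`                | extreme or suspiciously uniform whole profiles    |

The first five are context-free. The local outlier factor is context
dependent: it is the ratio of a subject's local density to that of its
`k` nearest neighbouring series (Euclidean distance on the imputed
series vectors), so it is ~1 for inliers and grows in sparse regions.
Numerical choices: autocorrelation is fixed at lag 1 (that is the lag on
which "add a constant to the previous value" manipulations show up);
LOF uses `k = min(20, n - 1)`; missing entries are imputed with the
per-visit median across the group before distances are computed, which
preserves per-visit location structure without inventing trends;
reachability distances are floored at 1e-12 so duplicated series do not
divide by zero; equality in the unique-value ratio is exact floating
equality, because rounding in the data is precisely the signal sought;
and the range of a length-one series is undefined rather than zero, so
single-visit groups do not flood the site tests with zeros.

## Scoring sites

`score_sites()` offers three methods:

* **Kolmogorov–Smirnov (`"ks"`)**: each site's feature values against
  the pooled values of all other sites, two-sided two-sample test. Sites
  of any size are tested, down to a single subject. R's default
  small-sample behaviour is used (exact null distribution when the
  product of sample sizes is below 10,000 and there are no ties).
* **Mixed effects (`"lmm"`)**: an intercept-only model with nested
  random intercepts (site within country within region; levels with one
  group are dropped) fitted with `lme4`. For each entity, draws are
  simulated from the conditional normal distribution of its random
  effect; the median `m` and standard deviation `s` of the draws give
  `p = 2 * pnorm(-|m - c| / s)`, where `c` is the median of the entity
  medians at that level. The robust centre matters: a handful of grossly
  anomalous sites drag the fitted grand intercept, and relative to that
  biased intercept every *compliant* site would "deviate from zero".
  Recentring on the median entity is a no-op on clean data (the centre
  is then essentially zero) and restores the expected flat false-positive
  behaviour under heavy contamination. Country and region p-values are
  reported but never used for site flagging.
* **Average (`"average"`)**: the baseline — site means of the feature,
  flagged when strictly outside `Q1 - 1.5 IQR` or `Q3 + 1.5 IQR`
  (boundary values are not outliers; fewer than four usable sites means
  no flags). It ignores site size, which is exactly why it is a useful
  benchmark and why its false-positive rate is high.

All raw p-values of one scoring run (all sites × features × groups for
one method) form a single family for the Benjamini–Yekutieli step-up
correction — the widest defensible family, hence the most conservative,
chosen because the same subjects' data are reused across the many
site-versus-rest comparisons. The score is `-log10` of the adjusted
p-value and a site × feature is flagged when its **maximum score across
groups** reaches the threshold (default 1.3, i.e. adjusted p ≈ 0.05).
The average method contributes no p-values; it flags when any group
flags.

## Subject-level screening

Sites without systematic bias can still contain anomalous subjects.
`subject_outlier_report()` embeds the subject distance matrix with
classical metric MDS into two dimensions (deterministic, no tuning;
axis signs fixed by the largest coordinate) and reports a per-subject
isolation statistic (mean distance to the `k` nearest neighbours).
`rank_extreme_subjects()` ranks subjects by `|value - median| / MAD` of
a feature — robust centre and scale, so a gross outlier cannot mask
itself by inflating the spread; zero MAD falls back to absolute
deviation with a warning, and ties break deterministically by subject
id. The two views tend to agree: the maximum-LOF subject is almost
always among the most isolated points.

## The synthetic generator

`generate_study()` emulates a cleaned multi-centre study extract:
region → country → site hierarchy, per-subject baselines, a linear
visit trend, Gaussian residual noise, optional rounding, per-visit
missingness, staggered enrollment (prefix-only subjects), unscheduled
visits and screening failures (which `clean_study()` removes). The
defaults — 2 regions, 4 countries, 20 sites, 15 subjects per site,
8 visits, 5% missing records, 20% staggered subjects, 5% unscheduled,
5% screening failures — were chosen once as a realistic mid-size
phase-II/III configuration; parameter presets (alanine
aminotransferase, creatinine, systolic blood pressure, weight) carry
field-plausible synthetic means and spreads, with weight and blood
pressure rounded coarsely as they are in practice. By default there is
**no** site, country or region effect: the validation protocol washes
out pre-existing site signal by permuting subjects across sites, so
every flag on un-injected data is a false positive by construction. A
`site_effect_sd` knob exists solely for mixed-model power
experimentation.

What the generator does *not* emulate: treatment-arm effects, correlated
parameters, non-Gaussian biology, informative missingness, and
heterogeneous site sizes (sites are equal by default, a deliberate
simplification — see limitations). Passing simulation tests on this
generator therefore demonstrate the machinery under idealised,
known-null conditions, not performance on any real study.

## The validation protocol

`run_validation()` repeats, for every method × anomaly type × degree
cell: permute subjects across sites, draw 3 target sites, apply the
type's transformation at the given degree, re-discover groups, compute
the feature *paired* with the anomaly type, score, and flag. True and
false positive rates are pooled across 100 iterations (sums of counts).
Detection is only counted on the paired feature (a mean-shift anomaly
must be caught by the mean feature, and so on); this is the strictest
reading of the pairing between transformations and features. Iteration
seeds are derived by hashing the base seed with the cell labels, so any
single scenario can be reproduced in isolation.

The six injectors scale their distortion by the site's pre-injection
mean of the parameter (all non-missing values at the site), which keeps
degrees comparable across parameters with different units. The
distributional ("lof") injector draws each affected subject's
replacement series from a pool — uniform over the subject's range, an
exponential shape, a near-constant, or a min/max two-point mixture —
and re-anchors it to the subject's original mean exactly (and, except
for the near-constant pool, the original range exactly), so only the
*shape* of the series changes. The duplication injector keeps the first
observation and replaces a round-half-up fraction of the rest; the
trending injector adds `degree` times the *original* predecessor (no
cascading), keeping the transformation linear.

Problem sizes used by the package's own simulation checks (chosen as
the package's standard demonstration scale): 100 null studies for the
false-positive control, 100 iterations per degree on the
{0.1, 0.25, 0.5, 1, 2} grid for the power curves, and 30 iterations for
the cross-anomaly-type comparison.

## Known limitations

* With equal-size sites the K-S method saturates at high degrees just
  like the others; its characteristic TPR deficit only appears when a
  study contains very small sites (a site of one or two subjects can
  hardly reach significance in a rank test). Benchmarks on the default
  generator therefore cannot separate the methods' TPR at extreme
  degrees.
* Proportional injection (`shift = degree × site mean`) makes a site
  whose pre-injection mean is randomly low receive a smaller absolute
  distortion — occasionally small enough for the mixed model to absorb,
  particularly when the few anomalous sites happen to cluster inside
  one country and the country-level random intercept soaks up their
  shift. This is the flip side of modelling the hierarchy: higher-level
  random effects control for demographic structure, but they can also
  explain away an anomaly cluster that aligns with that structure.
* Only numeric measurements are supported; categorical, ordinal or date
  data must be transformed to numbers upstream.
* The mixed model assumes Gaussian residuals and random effects;
  heavy-tailed features (LOF in particular) violate this.

## Reproducing the headline numbers

`scripts/acceptance.R` rebuilds the deterministic grouping fixture and
recomputes the two worked-example group sizes from scratch:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The testthat suite (`tests/testthat/`) contains the full set of oracle
comparisons, calibration checks and simulation benchmarks described
above.
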