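Package: sitespotter
Title: Site-Level Anomaly Detection for Clinical Trial Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Unsupervised statistical data monitoring for clinical trials.
    Discovers groups of equal-length subject time series per measurement
    parameter, summarises each series into six scalar features (mean,
    standard deviation, range, unique-value ratio, lag-1 autocorrelation,
    local outlier factor), and scores investigation sites for systematic
    data anomalies with three methods: a two-sample Kolmogorov-Smirnov
    test, a nested-random-intercept mixed-effects model, and an
    interquartile-range rule on site mean feature values. P-values are
    corrected with the Benjamini-Yekutieli procedure and reported as
    -log10 anomaly scores. Includes subject-level outlier screening via
    similarity-plot coordinates, a six-type site anomaly injector, a
    synthetic long-format study generator, and a simulation harness that
    estimates true and false positive rates of site flagging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
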