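Package: gaitagree
Title: Agreement Analysis for Two-System Gait Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Method-comparison statistics for validating a wearable gait
    measurement system against an optoelectronic reference. Implements
    normality-gated two-tailed paired tests (Shapiro-Wilk gate selecting a
    paired t-test or Wilcoxon signed-rank test), Passing-Bablok
    non-parametric regression with rank-based confidence intervals and a
    cusum linearity check, Bland-Altman bias and limits-of-agreement
    analysis with trend diagnostics, and a deterministic classification of
    systematic measurement error (constant, proportional) into agreement
    levels. Includes a synthetic generator of paired spatiotemporal gait
    data with known error structure, Monte-Carlo calibration utilities,
    tidy() and glance() methods, and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
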