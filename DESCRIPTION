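Package: corrlit
Title: Mining, Auditing and Modelling Published Correlational Effect Sizes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for meta-research on Pearson correlations reported in the
    scientific literature. Extracts "r(df) = x, p = y" style reports from
    plain-text article bodies and validates extraction recall against
    annotated synthetic corpora; audits reported significance labels against
    exact critical boundaries of the correlation test; summarises effect-size
    distributions (quartiles, cumulative percentiles by maximum degrees of
    freedom, rolling group medians, bootstrap confidence intervals for
    medians, yearly Spearman correlations of effect size with sample size);
    computes exact p-values, null expectations for non-significant
    correlations, and exact statistical power and required sample sizes for
    correlation tests under the bivariate-normal model; and generates
    synthetic literatures with known ground truth (null/non-null effect
    mixtures, heavy-tailed sample sizes, significance-dependent text
    emphasis, misreporting) for calibration and pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    utils,
    withr
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
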