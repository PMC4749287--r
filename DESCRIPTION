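Package: twindelta
Title: Genetic and Environmental Decomposition of Longitudinal Change in Twin Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the classical twin analysis of longitudinal change
    scores (delta-phenotypes). Simulates monozygotic/dizygotic twin cohorts
    with a known additive-genetic, dominance, shared- and unique-environment
    architecture for both phenotype level and change; applies standard
    cleaning rules (log transform, 3-SD outlier masking) and builds change
    scores; tests mean change with a mixed-effect kinship model; estimates
    zygosity-specific intra-pair correlations of change by maximum
    likelihood; and decomposes the variance of change into ACE/ADE
    components with likelihood-ratio nested-model selection, AIC, and
    bootstrap confidence intervals. All user-facing functions take and
    return tibbles so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
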