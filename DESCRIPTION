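Package: regimap
Title: Registry Incidence Trends, Age-Period-Cohort Decomposition, and
    Stabilized Disease Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the analysis of population-based cancer-registry
    incidence tables: direct age standardization with the WHO 2000 world
    standard population, average annual percent change (AAPC) trend
    estimation with joinpoint selection, age-period-cohort decomposition
    under a constant-relative-variation identifiability constraint,
    standardized incidence ratios with empirical-Bayes shrinkage toward
    the null, and heteroscedastic ordinary kriging for stabilized disease
    maps.  Includes a synthetic multi-area registry generator with known
    age, period, cohort and spatial structure so that every pipeline stage
    can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    mgcv,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
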