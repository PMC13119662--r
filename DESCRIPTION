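Package: hgrisk
Title: Tissue-Specific Mercury Bioaccumulation and Dietary Risk Assessment
    for Freshwater Fish Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing total-mercury (THg) concentrations measured
    across multiple organs of freshwater fish and for translating muscle
    concentrations into human dietary risk. Implements descriptive and
    comparative tissue statistics (normality-gated transforms, one-way ANOVA
    with Tukey HSD, Pearson/Spearman size-concentration correlations, OLS
    size models, exact Mann-Whitney size-class contrasts), deterministic
    exposure metrics (estimated daily intake, target hazard quotient, hazard
    index, safe weekly intake with traffic-light advisory categories), and a
    probabilistic Monte Carlo exposure engine with triangular intake sampling
    and species-specific empirical bootstrap of concentrations. A calibrated
    synthetic fish-survey generator reproduces the statistical structure of a
    cascade-reservoir survey so the full pipeline is testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    readr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
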