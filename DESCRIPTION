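Package: crowdmix
Title: Mixture Models of Orientation-Report Errors in Visual Crowding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of continuous-report orientation data from visual
    crowding experiments. Implements three nested mixture models of the
    report-error distribution on the 180-degree orientation circle (a von
    Mises target component plus uniform guessing; an added local
    flanker-misreport component; an added global-configuration misreport
    component), multi-start maximum-likelihood fitting with AICc model
    comparison, per-observer and group-level statistics (repeated-measures
    ANOVA with Greenhouse-Geisser correction, Bonferroni pairwise tests,
    paired t-tests with Cohen's d), a perpendicular-global control fit, and
    a synthetic-data generator emulating the experimental design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    dplyr,
    jsonlite,
    lhs,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
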