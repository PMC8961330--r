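Package: famload
Title: Continuous Familial Loading Scores for Depression and Anxiety
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes the continuous familial loading score (FLS), an
    age-adjusted likelihood-ratio index of familial risk for depression
    and anxiety built from Family Tree Inventory style reports on
    first-degree relatives, together with the dichotomous family-history
    (FH) indicator. Includes a liability-threshold synthetic cohort
    generator with case ascertainment, and the accompanying statistical
    pipeline: wave-averaging of repeated outcomes, covariate-adjusted
    standardized regressions, FH-residualized FLS analysis, point-biserial
    and Pearson correlations, pooled-variance t tests, 2x2 chi-square
    tests, and Benjamini-Hochberg false discovery rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0), withr, yaml, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
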