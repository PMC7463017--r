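Package: eractivity
Title: Oestrogen Receptor Pathway Activity Scoring and Cohort Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers oestrogen receptor (ER) pathway activity from target-gene
    mRNA measurements with a two-layer Bayesian network, calibrates the
    network on ground-truth active/inactive samples, normalises qPCR Cq
    values against reference genes, and runs the downstream cohort
    statistics used in endometrial-cancer studies: group comparisons
    (ANOVA with Tukey HSD, Mann-Whitney, chi-squared), immunohistochemistry
    and activity-quartile risk grouping, Kaplan-Meier/log-rank survival
    curves and Cox proportional-hazards regression. Includes a synthetic
    cohort generator that emulates the calibration design and the clinical
    cohort structure so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    survival,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
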