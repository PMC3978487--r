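Package: poolmark
Title: Pooled Survival Meta-Analysis of Dichotomized Expression Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-dataset prognostic marker screening for expression cohorts.
    Expression of a gene (or of the host gene of an intronic microRNA) is
    dichotomized at the median or at a quartile within each cohort, the
    resulting high/low group assignments are pooled across cohorts without
    any cross-dataset value adjustment, and the pooled two-group cohort is
    analysed by Kaplan-Meier estimation, the log-rank test and Cox
    proportional-hazards regression. Includes clinical filtering,
    nearest-centroid molecular-subtype stratification with pluggable centroid
    tables, multi-marker combination rules, a consensus-significance sweep,
    and a seeded multi-cohort simulator with known prognostic structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
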