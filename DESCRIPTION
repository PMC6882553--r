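Package: dscale
Title: Linking Child-Development Instruments to a Common Interval Scale
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a common interval scale for early childhood development
    (the D-score) from heterogeneous item-level assessment data. Provides an
    item bank with cross-instrument equate groups, harmonisation of raw
    instrument scores into a sparse binary response matrix, Rasch item
    difficulty estimation by pairwise conditional likelihood with
    equate-group equality constraints, infit/outfit item-fit statistics and
    retention rules, differential item functioning checks across countries,
    expected a posteriori (EAP) ability scoring on an anchored D-score
    metric, LMS (Box-Cox) age-conditional references yielding
    D-score-for-age z-scores (DAZ), discriminant/concurrent/predictive
    validity analyses, and a synthetic multi-cohort data generator with
    known truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
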