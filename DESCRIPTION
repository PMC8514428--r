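Package: OncoProp
Title: Incidence-Weighted Pan-Cancer Gene Mutation Proportions
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates the proportion of all newly diagnosed cancers in a
    population that carry a coding mutation in each gene, by weighting
    per-cancer-type mutated fractions from tumor-sequencing cohorts with
    registry incidence shares. Provides a common cancer taxonomy layer that
    reclassifies ICD-O-3 morphology/site code pairs and study sample
    metadata onto shared categories, MAF-style mutation-call ingestion with
    a coding-mutation class filter, longitudinal and cross-study patient
    deduplication, gene-symbol standardization, the weighted estimator
    G = C %*% S' with per-category contribution breakdowns, subclass and
    multi-gene union analyses, Poisson-replicate 95% confidence intervals,
    and a synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: SomaticMutation, Epidemiology, StatisticalMethod, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
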