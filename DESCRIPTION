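Package: riskclust
Title: Density-Based Discovery of Subgroups in High-Risk Patient Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering distinct subgroups of
    high-risk patients from mixed-type administrative and electronic health
    record feature tables. Cohorts are reduced to two dimensions with an
    exact t-distributed stochastic neighbor embedding (t-SNE) and clustered
    with the density-based OPTICS algorithm, which retains unclusterable
    patients as outliers rather than forcing assignment. Clusters are
    characterized by one-versus-rest ridge regressions across a penalty
    grid, with coefficient-range variable importance and automated label
    evidence. Includes feature preparation (median aggregation of repeated
    measures, proportion-of-days-covered medication adherence, low-variance
    and correlation pruning, chained-equations imputation), risk-stratified
    subsampling, per-cluster outcome summaries, and a synthetic cohort
    generator with planted subgroup structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
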