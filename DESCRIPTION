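Package: evdx
Title: Plasma Extracellular Vesicle Tau-Ratio and TDP-43 Diagnostic Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for two-marker molecular-pathology
    classification in frontotemporal dementia (FTD), amyotrophic lateral
    sclerosis (ALS) and progressive supranuclear palsy (PSP) from plasma
    extracellular-vesicle (EV) biomarkers: the 3R/4R tau isoform ratio and
    TDP-43 concentration. Provides seeded synthetic cohort generation
    calibrated to published group medians and interquartile ranges,
    nonparametric group comparisons (Kruskal-Wallis with Dunn's pairwise
    correction), Spearman correlation matrices, monotone trend fits, ROC
    analysis with Hanley-McNeil standard errors, prevalence-adjusted
    precision-recall curves, univariate Gaussian mixture fitting by EM with
    parametric-bootstrap selection of the number of components, data-driven
    cut-offs at component density crossings, a two-marker classification
    grid, diagnostic performance with exact Clopper-Pearson intervals, and
    cross-cohort cut-off transfer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC
Config/testthat/edition: 3
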