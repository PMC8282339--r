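Package: pHflux
Title: Intracellular pH Dynamics, Net Acid Extrusion and Prognostic
    Meta-Analysis for Breast Tissue Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intracellular pH regulation in freshly isolated
    breast tissue organoids from ratiometric (BCECF-type) fluorescence
    traces recorded during NH4+-prepulse experiments: calibration,
    protocol segmentation, intrinsic and CO2/HCO3- buffering capacity,
    and net acid extrusion flux curves with the transport rate extracted
    at pH 6.5-6.6. Includes a mechanistic trace simulator with known
    transporter fluxes, a clinicopathological cohort simulator with
    configurable odds ratios, the cohort statistical battery
    (mixed-effects paired comparisons, trend tests, multiple linear and
    binomial/ordinal logistic regression), and a transcriptomic survival
    meta-analysis (probe collapse, double cross-sample standardization,
    nearest-centroid molecular subtyping, z-score-stratified
    Kaplan-Meier comparison with log-rank, Gehan-Breslow-Wilcoxon and
    Mantel-Haenszel hazard ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    survival,
    MASS,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
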