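Package: cpapnet
Title: Patient Compatibility Networks for CPAP Treatment Response in Sleep Apnea
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Network-medicine analysis of continuous positive airway pressure
    (CPAP) treatment response in obstructive sleep apnea (OSA). Builds weighted
    patient risk-compatibility networks from six discretized clinical
    parameters (gender, age group, blood pressure, obesity, neck circumference,
    sleepiness), detects phenotype communities by modularity maximization with
    an exhaustive small-graph oracle and a force-directed layout diagnostic,
    cross-tabulates apnea-hypopnea index (AHI) severity transitions after
    one-night CPAP to label best/good response classes, and evaluates neck
    circumference as a screening and response indicator via ROC/AUC analysis,
    Youden-optimal cutoffs and likelihood-ratio tables. Includes a synthetic
    cohort generator emulating the marginal structure of the study cohorts so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
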