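Package: oigrowth
Title: Growth-Curve Reference Modelling and Treatment-Response Analysis for
    Osteogenesis Imperfecta Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing longitudinal growth and bone mineral density
    (BMD) in osteogenesis imperfecta (OI) cohorts against hospital controls.
    Provides age- and sex-stratified control selection, LOESS normal-growth
    reference curves, a normalised slope-angle statistic for quantifying
    treatment response between successive scans, stratified Wilcoxon
    signed-rank testing, hierarchical clustering of binary clinical traits
    with enrichment tests, HGVS cDNA variant parsing and consequence
    classification for the type I collagen genes COL1A1 and COL1A2, and a
    synthetic cohort generator so that every stage of the pipeline can be
    exercised with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
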