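Package: mesozoo
Title: Mesozooplankton Biomass Estimation and Community Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating taxon-specific mesozooplankton biomass from
    dried, formalin-preserved net samples and for analysing the resulting
    community data. Implements the full estimation chain from raw weighing
    records (control-based measurement-error subtraction, a reliability filter
    at a multiple of the control standard deviation, formalin mass-loss
    correction, and areal standardization through Motoda split and pipette
    subsampling fractions) to carbon and energy content via taxon-specific
    conversion factors. Includes a registry of published length-weight
    relationships for Calanus and Oithona with a framework for comparing
    calculated against measured individual dry weights, a multivariate suite
    (Hellinger transformation, principal component analysis, hierarchical
    clustering with cophenetic and Gower model selection, cluster-number
    diagnostics, species contribution analysis, and redundancy-analysis
    variation partitioning with a circular seasonal predictor), and a
    synthetic survey generator that reproduces the sampling chain for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    cluster,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
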