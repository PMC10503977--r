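Package: qsarkit
Title: Building and Validating 2D-QSAR Models for Enzyme Inhibitors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-dimensional quantitative structure-activity
    relationship (2D-QSAR) modelling of small-molecule enzyme inhibitors,
    built around a SummarizedExperiment-derived compound container. Covers
    descriptor screening (variance, response correlation, variance inflation
    factors), ordinary least-squares activity models with the standard fit
    statistics, the full internal/external validation battery (leave-one-out
    Q2, Roy's Rm2 metrics, Y-randomization with cRp2, Golbraikh-Tropsha
    criteria, Q2(F2)), a leverage-based applicability domain with Williams-plot
    classification, rule-based drug-likeness evaluation (Lipinski, Veber,
    Egan, Muegge, Ghose, Abbott bioavailability score), docking-score versus
    activity correlation, and a seedable synthetic-data generator for
    end-to-end testing. Ships a curated chalcone MAO-B inhibitor dataset as
    plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Cheminformatics, Regression, StructuralPrediction, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
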