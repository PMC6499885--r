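Package: nephrosig
Title: Quantitative Analysis Chain for Kinase-Inhibitor Nephrotoxicity Signals
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the quantitative stages used to characterize
    kinase-inhibitor nephrotoxicity from complementary data types:
    reporting-odds-ratio disproportionality analysis of adverse-event
    frequency tables with a dual-risk outlier profile; spectral-count
    differential phosphoproteomics with Benjamini-Hochberg control;
    seed-plus-intermediate subnetwork expansion over an evidence-weighted
    protein-protein interactome with a Monte Carlo resampling null; kinome
    residual-activity filtering and unique-inhibition detection; AFM
    force-curve elastography with pyramidal Hertzian contact mechanics and
    depth-dependent pointwise moduli; and four-parameter logistic
    dose-response fitting with geometric EC50 summaries.  A seeded
    synthetic-data module generates inputs with planted ground truth for
    every stage, and a pipeline driver runs the full chain on a scenario
    configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    parallel,
    stats,
    utils,
    igraph,
    minpack.lm,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
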