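Package: cytoBN
Title: Comparative Bayesian Network Analysis of Flow Cytometry Immune Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Secondary analysis of cell-level flow cytometry (FACS) data
    centered on discrete Bayesian networks. Provides equal-frequency
    discretization of compensated fluorescence intensities, BDeu
    (marginal-likelihood) scored structure learning with sparse candidate
    selection and random-restart hill climbing, marginal-likelihood edge
    strengths, Markov neighborhood and Markov blanket extraction around a
    clinical response node, sorted marker-configuration tables with
    frequency-dropoff cutoffs, indicator ("contrast") variable supergraphs for
    comparing immune networks across regimes (responder status, treatment
    day), threshold gating into major T-cell subsets, and per-marker
    two-sample distribution comparison via the 1-D Earth Mover's Distance and
    the energy distance. Includes a synthetic cohort generator emulating a
    small immunotherapy study so every pipeline stage can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: FlowCytometry, NetworkInference, GraphAndNetwork, ImmunoOncology
RoxygenNote: 7.3.3
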