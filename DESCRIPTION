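Package: pYtagKinetics
Title: Mass-Action Modeling and Quantification of pYtag RTK Biosensor Dynamics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic mass-action model of receptor tyrosine kinase (RTK)
    activation as read out by pYtag translocation biosensors: ligand binding,
    receptor dimerization/autophosphorylation (lumped), and recruitment of a
    tandem-SH2 reporter to ligand-bound receptor dimers. Provides analytic
    pre-stimulus equilibria, stiff ODE simulation of cytosolic reporter
    clearance, ligand tuning through dissociation-rate scale factors (beta,
    gamma), dose-response panels and kinetic regime classification, a
    glioblastoma-mutant scenario, expression-ratio sweeps, quantification of
    per-cell intensity timeseries (clearance activity, aberrant-frame repair,
    min-max normalization, time-to-half-max, KTR ratios, replicate
    aggregation), a seeded synthetic single-cell trace generator with ground
    truth, and least-squares recovery of ligand scale factors from clearance
    trajectories.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    jsonlite,
    yaml,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
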