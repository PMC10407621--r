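Package: roqsar
Title: QSAR Modeling of Organic Micropollutant Rejection by Reverse-Osmosis Membranes
Version: 0.1.0
Authors@R:
    person("roqsar", "developers", email = "roqsar@example.org", role = c("aut", "cre"))
Description: Tools for quantitative structure-activity relationship (QSAR)
    modeling of emerging-contaminant rejection by reverse-osmosis membranes.
    Computes topological and geometrical molecular descriptors (structural
    information content, edge-adjacency spectral moments and eigenvalues,
    GETAWAY R autocorrelations) directly from SMILES or SDF input, implements
    a descriptor filtering cascade (zero-variance removal, correlation
    pruning, forward stepwise ranking), fits a 4-4-1 back-propagation
    feedforward neural network by Levenberg-Marquardt with early stopping and
    a multiple linear regression baseline, quantifies descriptor importance
    with Garson's connection-weight algorithm, and assesses the applicability
    domain with leverage statistics and Williams-plot exports. Ships the
    72-compound rejection dataset used throughout as a plain-text fixture,
    plus a synthetic-data generator with known ground truth for end-to-end
    pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
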