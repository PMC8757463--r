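Package: hxmap
Title: Hydrogen-Deuterium Exchange Prediction from Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts site-resolved hydrogen-deuterium exchange (HDX)
    observables from conformational ensembles of proteins. Computes
    per-frame amide protection states from geometric hydrogen-bond and
    burial criteria, weighted exchange free energies (dG_HX) with
    bootstrap uncertainties, denaturant dependence via conformational
    reweighting (m-values, m_closed/m_open decomposition, opening-class
    assignment), Linderstrom-Lang exchange kinetics (EX1/EX2 diagnostics,
    protection factors, multi-pathway flux), free-energy surfaces on
    (Rg, H-bond count) or contact-map principal components with an MBAR
    solver for replica-exchange data, and a trajectory-truncation
    protocol for irreversibly folding proteins. Includes a synthetic
    multi-state ensemble generator with exact analytic ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
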