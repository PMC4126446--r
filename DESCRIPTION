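Package: lobulesim
Title: Agent-Based Simulation of Liver Lobule Inflammation and Fibrosis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A multiscale agent-based model of chronic liver inflammation
    and fibrosis. A patch of liver tissue is represented as a honeycomb of
    hexagonal lobules whose septa form a mechanical skeleton of paired
    boundary segments with prismatic and revolute joints. Hepatocytes,
    Kupffer cells, hepatic stellate cells, portal fibroblasts and
    myofibroblasts interact through diffusible mediators (TNF-alpha,
    TGF-beta1, HMGB1) under literature-style threshold rules; repeated
    centrilobular injury drives Kupffer activation, M1-to-M2 polarization,
    myofibroblast activation and progressive collagen deposition. A
    non-perturbing virtual elastography probe scores tissue stiffness as
    mean internal-node displacement after an inward impulse, and in silico
    therapy experiments (anti-TNF, enhanced M2 activation) can be compared
    against untreated baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
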