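Package: afablate
Title: In Silico Trials of Atrial Fibrillation Ablation Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale virtual trials of catheter ablation for atrial
    fibrillation on synthetic left-atrial surface models. Generates seeded
    virtual patients (triangulated atrial shells with region labels, a
    two-coordinate surface chart, fiber fields and late-gadolinium-enhancement
    intensity maps), translates imaging intensity into conduction and ionic
    heterogeneity, simulates anisotropic monodomain excitation with a
    phenomenological ionic surrogate, maps phase singularities and driver
    hotspots, plans six automated ablation lesion sets (pulmonary vein
    isolation, posterior box, fibrosis- and hotspot-targeted), classifies
    acute outcomes by dominant frequency, computes lesion metrics, and trains
    a random-forest acute-responder classifier with Shapley feature
    attributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    ranger,
    e1071,
    glmnet,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
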