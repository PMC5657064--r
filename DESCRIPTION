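Package: combifuse
Title: Predicting Combinative Drug Pairs by Fusing Heterogeneous Drug Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Drug-driven prediction of combinative (synergistic) drug pairs
    from heterogeneous per-drug evidence: a spectral embedding of the
    pharmaceutical drug-drug interaction network, first-level ATC code
    Tanimoto similarity, and sparse binary drug-target and side-effect
    profiles. Drug pairs are featurized symmetrically, scored per channel
    with probabilistic logistic classifiers, and the per-channel confidence
    scores are late-fused (mean, AUC-weighted, or grid-searched weights).
    Includes scenario-aware cross-validation for realistic screening
    (known-known, known-new, new-new pairs), ranking evaluation by AUC and
    AUPR, channel-wise separability diagnostics, and a synthetic benchmark
    generator with planted channel signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
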