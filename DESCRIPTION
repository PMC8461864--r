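Package: clinCMap
Title: Clinical Connectivity Mapping for Drug Repurposing from Longitudinal Lab Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Connectivity-map style drug repurposing driven entirely by clinical
    laboratory results. Estimates ternary drug-to-lab effect vectors from
    longitudinal prescription/lab histories with a continuous self-controlled
    case series model (within-patient centering plus an L1 penalty), estimates
    ternary disease-to-lab sign vectors from case/control survey data with
    Wilcoxon rank-sum tests, scores drug-disease pairs by the negative dot
    product of the two sign vectors, and evaluates rankings against a
    gold-standard indication list with precision at K and fold-enrichment
    statistics. Includes seeded synthetic-data generators with planted effect
    directions so the whole pipeline is testable without external data, and a
    spectral co-clustering view of the score matrix.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
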