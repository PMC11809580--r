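Package: taxonstab
Title: Stability of Phylogenetic Inference Under Single-Taxon Addition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Leave-one-out analysis of phylogenetic tree stability under
    taxon addition. Quantifies whether and where an inferred tree topology
    changes when one taxon is added to an alignment, using the taxon
    influence index (Robinson-Foulds distance between the pruned and the
    re-inferred tree), a disruption radius locating topology changes
    relative to the attachment point, and topology tests (approximately
    unbiased test via multiscale bootstrap, Shimodaira-Hasegawa test) for
    the significance of instability. Computes maximum-likelihood placement
    of a query taxon with likelihood weight ratios, a battery of summary
    statistics describing the placement, and class-balanced random-forest
    ensembles that predict instability from those statistics. Includes a
    synthetic-data generator producing alignments evolved on known trees
    with controllable signal strength, low-support regions, mosaic taxa
    and long pendant branches, so the whole pipeline is testable with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    pROC,
    ranger,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
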