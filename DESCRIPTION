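Package: MorphoMask
Title: Partition-Signal Experiments on Morphological Character Matrices
    under Maximum Parsimony
Version: 0.3.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing the phylogenetic signal carried by a
    character partition (e.g. the postcranial skeleton) in discrete
    morphological matrices. Reads and writes TNT-dialect matrices,
    scores trees under Fitch parsimony for unordered equally weighted
    characters, runs heuristic most-parsimonious-tree searches with
    random addition sequences and NNI/SPR/TBR branch swapping, computes
    strict consensus, bootstrap and Bremer support, ensemble consistency
    and retention indices, and enumerates unambiguous synapomorphies
    from exact most-parsimonious reconstructions. A masking/transfer
    experiment layer builds partition-masked and score-transferred
    matrix variants, classifies the placement of a focal clade, and
    compares topologies across analyses. An Mk-style simulator with
    planted clade markers, partition-specific homoplasy and fossil-like
    missing data provides ground-truth matrices for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
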