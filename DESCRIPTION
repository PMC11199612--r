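Package: pksline
Title: Polyketide Structure Prediction from Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts mature type I cis-AT polyketide structures from
    annotated biosynthetic gene clusters (BGCs) and validates candidate
    structures against tandem mass spectra. The pipeline covers
    acyltransferase substrate-specificity classification from 24-residue
    active-site signatures with an extremely-randomized-trees model,
    docking-domain based assembly-order inference with a pairwise
    nearest-neighbour logistic model and permutation ranking, rule-based
    substrate maturation (KR/DH/ER reduction ladder), combinatorial core
    assembly and tailoring-modification application by subgraph matching,
    in-silico fragmentation spectral scoring in exact and mass-shift
    tolerant modes, and target-decoy false discovery rate estimation with
    edge-switching decoys.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mzR,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
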