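Package: shellphylo
Title: Species-Level Coding of Polymorphic Morphological Characters and
    Parsimony Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Turns individual-level, polymorphism-rich morphological
    observations (e.g., shell characters scored across hundreds of
    soft-shelled turtle specimens) into species-level phylogenetic
    codings, and evaluates the resulting matrices. Implements an
    ontogenetic screen based on Spearman rank correlation of character
    scores against relative skeletal maturity, frequency-threshold and
    maturity-based polymorphism reduction ("MinPoly") alongside a
    maximal-polymorphism alternative ("MaxPoly"), NEXUS/TNT matrix
    input and output with full polymorphism-dialect support, a
    parsimony engine (Fitch and Sankoff scoring of set-valued
    terminals, random-addition-sequence searches with TBR/NNI swapping,
    equal and implied weighting, secondary rooting, strict consensus),
    quartet-based topological accuracy scores (Estabrook categories and
    Strict Joint Assertions), and a synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
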