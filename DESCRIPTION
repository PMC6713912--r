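Package: hairpin3d
Title: MicroRNA Hairpin Classification from 3D Graphical Structure Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discriminates microRNA precursor hairpins from pseudohairpin
    decoys using a compact 36-dimensional descriptor of RNA secondary
    structure. Sequences are folded (built-in maximum-base-pairing dynamic
    program, or an external RNAfold-compatible folder), the dot-bracket
    structure is case-encoded onto the sequence, and each base is mapped to a
    corner of the cube defined by the three chemical dichotomies of RNA bases
    (purine/pyrimidine, amino/keto, strong/weak hydrogen bonding). The
    cumulative 3D curve of these vectors yields per-(base, pairing-state)
    geometric centers: the 36 features. Decision-tree, naive-Bayes, and
    random-forest classifiers are trained under balanced sampling with
    70/30 Monte Carlo cross-validation, and the best models can be saved and
    applied to new sequences. Includes a synthetic corpus generator
    (miRNA-like hairpins and dinucleotide-shuffled decoys) so the whole
    pipeline is testable without external data, plus a command-line
    interface for the fold/featurize/train/predict workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    randomForest,
    Rcpp,
    readr,
    rlang,
    rpart,
    e1071,
    stringr,
    tibble,
    tidyr,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
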