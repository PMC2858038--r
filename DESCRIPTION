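Package: rnaclad
Title: Structural Cladistics of RNA Secondary Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the evolution of structured RNA molecules
    (such as the RNase P RNA) directly from their secondary structures.
    Parses dot-bracket, CT and bpseq files, decomposes structures into
    typed substructures (stems, hairpins, bulges, internal loops,
    multiloop segments and free ends), codes substructure geometry as
    polarized linearly ordered multistate characters, and infers
    intrinsically rooted maximum-parsimony trees of molecules and of
    substructures using a hypothetical ancestor for rooting. Includes
    Wagner (ordered) and Fitch (unordered) parsimony scoring, exhaustive,
    branch-and-bound and heuristic (random addition + TBR) searches,
    consistency/retention/rescaled indices, g1 tree-length skewness,
    fast-stepwise-addition bootstrap, NEXUS interchange with ANCSTATES
    polarization, node-distance ancestry chronologies, cumulative
    accretion curves and evolutionary heat maps, plus a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
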