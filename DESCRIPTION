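Package: cladatom
Title: Parsimony Analysis of Morphological Matrices with Compound-Character
    Atomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for maximum-parsimony analysis of discrete morphological
    character matrices, built around the question of how recoding compound
    characters into logically independent atomic characters affects tree
    length and character conflict. Reads and writes NEXUS and TNT matrices
    (including polymorphic, missing and inapplicable cells), scores trees
    under Fitch (unordered) and Wagner (ordered) parsimony with ensemble
    consistency and retention indices and implied-weights fit, performs
    random-addition-sequence heuristic search with NNI/SPR/TBR branch
    swapping as well as exhaustive search on small taxon sets, computes
    strict and majority-rule consensus trees and nonparametric bootstrap
    supports, maps synapomorphies and apomorphies onto optimal trees under
    ACCTRAN/DELTRAN resolution, and implements a character-jackknife
    experiment that compares matrices via tree-length decay regressions.
    A simulator for Mk-style discrete characters on random trees, with
    fossil-like taxon-biased missingness and artificial compound characters,
    provides matrices with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
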