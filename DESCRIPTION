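Package: siRNAtarget
Title: Target mRNA Secondary-Structure and Thermodynamic Features for
    siRNA Silencing Efficacy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Retrospective-analysis toolkit for the question of whether
    target-site secondary structure and siRNA:mRNA thermodynamics predict
    silencing efficacy.  Provides structure-element annotation of nested
    RNA secondary structures (stems, hairpin, internal, bulge, one-base
    bulge, multibranch and exterior loops), a desk-scale maximum-pair-weight
    folding engine with exact suboptimal enumeration, the H-b accessibility
    index over structure ensembles, nearest-neighbour duplex free energies
    and target-opening costs, GC-content binning, logistic-regression
    association testing with heteroskedasticity-robust confidence
    intervals, contingency and two-group tests, a seeded synthetic-study
    generator, and an end-to-end pipeline that reads FASTA, CT,
    dot-bracket, ss-count and delimited siRNA tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    sandwich,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
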