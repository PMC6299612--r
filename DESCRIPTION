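Package: pldfam
Title: Discovery, Curation and Gain/Loss Analysis of GDPD-Like SMase D/PLD Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling and analysing the GDPD-like sphingomyelinase
    D / phospholipase D (SMase D/PLD) protein family: screening of tabular
    similarity-search results with single- and multi-query E-value rules,
    sequence curation (redundancy, fragment, active-site divergence,
    contaminant and evidence-confidence filters), signature-based clade
    classification from the C-terminal plug motif, beta-alpha-1 loop length,
    catalytic-loop cysteine topology and DUF-B repeats, and reconciliation of
    gene-family presence/absence with a rooted species tree by Dollo loss
    counting and asymmetric-cost gain/loss optimisation. Includes a synthetic
    sequence and scenario generator so that every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
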