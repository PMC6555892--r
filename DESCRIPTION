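Package: minar
Title: Seed-Gene Connector Subnetworks and GWAS Candidate Evaluation
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Finds bounded-size subnetworks of a molecular interaction
    network that connect a maximal number of disease seed genes through a
    minimal number of connector genes, quantifies the non-randomness of the
    resulting network with a hypergeometric enrichment score and a
    degree-matched permutation null, and evaluates connector genes as
    disease candidates against GWAS summary statistics using flanking-window
    SNP assignment and linkage-disequilibrium-aware Bonferroni correction.
    Includes a synthetic-data generator with planted ground truth so the
    whole pipeline is testable offline, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
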