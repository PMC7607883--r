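Package: coalcensus
Title: Gene-Tree Discordance Census and Coalescent Mixture Estimation
    for Phylogenomic Ortholog Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Curation of BUSCO-derived single-copy ortholog sets
    (reading-frame correction, protein-length coefficient-of-variation
    filtering, branch-length outlier screening), a census of rooted
    gene-tree topologies with respect to subfamily monophyly, an exact
    binomial test of the symmetric-mismatch expectation under incomplete
    lineage sorting, chromosome-arm (Muller element) stratification of
    topology frequencies, multispecies-coalescent simulation of gene
    trees on species trees and one-reticulation networks with sequence
    evolution and BUSCO-style artifact injection, and a moment estimator
    that inverts rooted quartet topology frequencies to an internal
    branch length in coalescent units and an introgression inheritance
    probability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    phangorn,
    seqinr,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
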