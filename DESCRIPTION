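Package: clonecall
Title: Clone Calling and Diversity Analysis for SNP-Fingerprinted Germplasm Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deduplicates clonally propagated germplasm collections from SNP
    allele-dosage fingerprints. Applies marker and sample quality filters,
    computes pairwise Hamming (allele-sharing) genetic distances, calibrates a
    duplicate-calling threshold from biological and technical replicate pairs,
    and partitions samples into clonal groups by single linkage. Downstream
    summaries cover zone-level sharing accounting, Shannon diversity of clone
    abundances, Weir-Cockerham and Nei Fst, Nei standard genetic distance with
    neighbor-joining trees, PCA and discriminant analysis of principal
    components (DAPC), minimum spanning networks with tie reticulations, and
    ordinal farmer-survey trait analysis. A synthetic-data generator produces
    zone-structured genotype collections with planted clones, replicate pairs,
    genotyping error and correlated survey scores, together with truth tables
    for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ape,
    igraph,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
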