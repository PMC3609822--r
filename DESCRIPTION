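Package: mtphylogeo
Title: Phylogeography of mtDNA Haplotypes with Riverine-Barrier Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for mitochondrial control-region phylogeography of
    structured animal populations. Collapses aligned per-sample sequences
    into haplotypes, computes pairwise-difference and Tamura-Nei (TN93)
    distances, builds neighbor-joining haplotype trees with site-bootstrap
    support and support-threshold collapsing, extracts haplogroups, and
    estimates within-population diversity (haplotype diversity, mean
    pairwise differences, nucleotide diversity), pairwise Phi-ST with
    permutation tests, AMOVA variance partitions, and net population
    distances. A riverscape module measures straight great-circle
    distances, river-crossing counts, and headwater-detoured distances
    over a polyline river map, and a barrier-inference module compares
    genetic against geographic distance with Pearson correlations,
    Kolmogorov-Smirnov normality checks, and Gaussian-GLM/AIC model
    selection. A synthetic landscape-genetics generator makes the whole
    pipeline runnable and testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vegan
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
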