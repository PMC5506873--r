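Package: biaslens
Title: Comparative Sequence, Structure and Phylogenetic-Signal Analysis of
    Paired [FeFe]-Hydrogenases
Version: 0.1.0
Authors@R:
    person("Biaslens", "Developers", email = "biaslens@example.org",
           role = c("aut", "cre"))
Description: A pipeline for locating candidate structural determinants of
    catalytic bias between two related [FeFe]-hydrogenases. Provides
    motif-based hydrogenase classification with accessory iron-sulfur
    cluster ligand inventories, per-column conservation profiling of a
    focal sequence pair against a homolog alignment, least-squares
    structural superposition and residue-to-cofactor proximity filtering,
    Blomberg's K phylogenetic signal with permutation p-values, a
    neighbor-joining fallback tree builder, efficiency-corrected qPCR
    relative quantification, and seeded synthetic-data generators that
    give every stage inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    Rcpp,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
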