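Package: corescan
Title: Bipartite ECF Sigma-Factor Promoter Scanning and Cys-Rich Domain Census
Version: 0.1.0
Authors@R: person("Core", "Scan Developers", role = c("aut", "cre"),
    email = "corescan@example.org")
Description: Infers a bipartite -35/-10 degenerate promoter consensus from a
    set of co-regulated genes, scans whole bacterial genomes for the motif
    under an explicit IUPAC mismatch budget, and applies a three-stage filter
    cascade (strand orientation relative to the downstream gene, invariant
    -35 positions, -10 anchor within a spacer window) to predict regulon
    members. Also provides a census of extracytoplasmic-function (ECF) sigma
    factors carrying a cysteine-rich C-terminal domain (CRD), alignment-based
    column conservation classes, and pairwise gene-neighborhood (synteny)
    comparison. A seeded synthetic-data module generates genomes, annotations
    and proteomes with planted ground truth so every stage is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
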