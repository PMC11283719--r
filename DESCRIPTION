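Package: virosag
Title: Simulation and Analysis of Gel-Bead Single-Virus Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates viral communities encapsulated in agarose gel beads,
    whole-genome amplification with multiple-displacement-amplification bias,
    read generation and per-bead contig formation, and implements the
    downstream single-virus genomics analysis: Poisson loading statistics and
    concentration estimation, amplification-bias metrics (Lorenz curve, Gini
    coefficient), per-bead contig binning and decontamination into viral
    single-amplified genomes (vSAGs), species-level vOTU clustering by
    ANI/aligned-fraction criteria, protein clustering and protein-sharing
    viral-cluster networks via Markov clustering, taxonomy voting, auxiliary
    metabolic gene (AMG) sharing statistics, and strain-level core/flexible
    comparative genomics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    igraph,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
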