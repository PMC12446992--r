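Package: cubscreen
Title: Codon Usage Bias Indices and Cross-Species Adaptation Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes per-gene codon usage bias indices (RSCU, ENC, SCUO,
    GC1/GC2/GC3, PR2 coordinates) and host-adaptation indices (CAI, RCDI,
    SiD) from coding-sequence FASTA files; screens one organism's genes for
    codon usage significantly correlated with a partner organism's usage
    profile; and integrates the resulting gene set with expression data via
    DEG-call merging, short-series model-profile clustering with exact
    permutation nulls, and 2^-ddCt relative quantification. Includes a
    seeded synthetic-data generator producing CDS collections with planted
    host-similar genes and negative-binomial count matrices with planted
    expression profiles, so every stage can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
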