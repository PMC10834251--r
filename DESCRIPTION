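Package: spliceshift
Title: Alternative-Splicing Meta-Analysis, Rescue Classification and
    Allele-Specific Expression for CAG-Expansion Ataxia Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying per cent spliced in (PSI) from splice
    junction counts, testing differential splicing with dual
    FDR/p-value significance thresholds, harmonizing significant events
    across multiple RNA-seq datasets (sharing-degree counts, upset-style
    membership matrices, PCA of shared-event PSI), classifying
    therapeutic rescue of missplicing from control/disease/treated PSI
    triples, quantifying allele-specific expression with
    discriminating-site references, hypergeometric gene-set
    over-representation, and a seeded junction-count simulator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: AlternativeSplicing, RNASeq, DifferentialSplicing, Software
RoxygenNote: 7.3.3
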