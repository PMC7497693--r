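Package: kinact
Title: Kinome Peptide-Array Analysis with Permutation-Based Upstream Kinase Scoring
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for tyrosine-kinase peptide microarray data in
    hormone-receptor-defined breast cancer subgroups. Provides array
    preprocessing (saturation masking, technical-replicate collapsing,
    detection filtering), per-substrate differential phosphorylation with
    peptide clustering, permutation-based upstream kinase analysis
    (significance and specificity Q-scores from sample-label and
    substrate-set permutations), and an expression-cohort integration stage
    (differential expression, kinome-gene signature clustering,
    Kaplan-Meier/log-rank survival comparison, candidate intersection).
    Includes seeded synthetic-data generators emulating the array and cohort
    designs, with ground truth exposed for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
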