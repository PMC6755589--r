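Package: sbdfp
Title: Statistical-Based Database Fingerprints for Compound Set Comparison
    and Similarity Searching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Condenses a compound data set into a single binary fingerprint
    by testing, bit by bit, whether the bit's "1"-frequency in the set is
    statistically higher than in a large reference collection (one-sided
    pooled two-proportion Z-test), alongside the classic 50%-threshold
    database fingerprint. Includes Tanimoto-based inter-dataset similarity
    matrices (all-compound-comparison, DFP and SB-DFP methodologies),
    complete-linkage clustering with Adjusted Rand Index evaluation against
    a ground-truth partition, and a repeated-random-query similarity-search
    benchmark (1-NN, DFP and SB-DFP strategies; recovery rate and ROC AUC).
    A seeded synthetic bit-matrix generator with planted enriched bits makes
    every component testable without chemical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mclust,
    ape
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB,
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
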