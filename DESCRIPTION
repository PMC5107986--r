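Package: refstab
Title: Reference Gene Screening and Expression-Stability Evaluation for qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens candidate reference (housekeeping) genes from RNA-Seq
    abundance tables by mean-expression and coefficient-of-variation
    thresholds, and evaluates their quantitative real-time PCR expression
    stability with four algorithms: geNorm expression-stability values (M)
    with pairwise-variation analysis V(n/n+1), the NormFinder model-based
    combination of intra- and inter-group variation, BestKeeper descriptive
    statistics and index correlation, and the comparative delta-Ct method.
    Per-algorithm rankings are integrated into a RefFinder-style consensus by
    the geometric mean of ranks. Includes standard-curve amplification
    efficiency estimation, target-gene normalization with ANOVA-based
    validation of alternative reference sets, and a synthetic-data generator
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
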