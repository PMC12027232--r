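Package: refstab
Title: Reference Gene Selection and Stability Analysis for RT-qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens candidate reference (housekeeping) genes from an RNA-seq
    TPM matrix using four expression-stability criteria and a coefficient-of-
    variation shortlist, scores candidates from RT-qPCR Cq data with four
    stability statistics (comparative delta-Ct, geNorm M-value with pairwise
    variation, NormFinder variance decomposition, BestKeeper descriptive
    index), aggregates the per-method ranks into a comprehensive geometric-mean
    ranking, and normalizes target-gene expression by the 2^-ddCt method
    against one or more selected references. Includes seeded generators for
    synthetic TPM and Cq matrices with planted stable and unstable genes, so
    the whole pipeline can be exercised and validated by parameter-recovery
    experiments without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
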