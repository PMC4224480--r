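Package: metamark
Title: Metabolomic Biomarker Discovery from Multi-Platform Mass-Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A case-control biomarker discovery pipeline for untargeted
    LC-HRMS and GC-MS metabolomics feature tables. Provides feature-level
    quality filters (abundance, mass defect, contaminants, presence),
    internal-standard normalization, Welch t-test screening with
    Benjamini-Hochberg false discovery rates, exact-mass ESI adduct
    annotation against a formula database, and a nested cross-validation
    classification core with recursive feature elimination, resample-averaged
    VIP (variable importance in the projection) ranking for PLS-DA and
    linear-SVM models, independent-validation feature stepping, and a
    permutation null. A synthetic multi-platform cohort generator with known
    planted effects makes every stage testable without real plasma data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
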