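Package: ratclocks
Title: Epigenetic Clocks and Multi-Organ Methylation Aging Analysis for
    Rat RRBS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing epigenetic aging from reduced
    representation bisulfite sequencing (RRBS) methylation data across
    multiple organs. Reads Bismark coverage and CGmap methylation calls,
    assembles sample-by-CpG methylation matrices with coverage-based
    masking and filtering, trains elastic-net epigenetic clocks
    (including a per-sample intersection clock and an rDNA-restricted
    clock with mean/KNN/SoftImpute/PCA imputation and a model grid over
    elastic net, gradient boosting and random forest), computes global
    mean methylation and mean methylation entropy, performs strand-aware
    promoter differential-methylation analysis with Bonferroni and
    Benjamini-Hochberg correction, and runs paired multi-organ
    comparisons of epigenetic age acceleration. A synthetic methylome
    generator with recorded ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    randomForest,
    xgboost,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
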