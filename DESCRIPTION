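Package: cfmethdx
Title: Cell-Free DNA Methylation Marker Discovery and Diagnostic Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating blood-based cancer diagnostics
    from targeted bisulfite sequencing of circulating cell-free DNA. Implements
    read-level co-methylation scoring (fraction of reads carrying at least three
    methylated CpGs within a sliding window of three to five CpG sites),
    rank-sum marker discovery with Benjamini-Hochberg false discovery control,
    tissue-plasma concordance filtering via moderated t-statistics with
    empirical-Bayes variance shrinkage, diagnostic panel selection by repeated
    LASSO stability counts intersected with repeated cross-validated random
    forest importance, random-forest diagnostic modelling with stage-stratified
    ROC/PRC evaluation, mammography combination, and clinicopathologic
    association scans. A synthetic cohort generator emulating matched
    tissue/plasma pairs and case/control plasma cohorts makes every stage
    testable without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    pROC,
    ranger,
    stats,
    utils,
    withr
Suggests:
    limma,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
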