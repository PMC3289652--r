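Package: diffpairs
Title: Normalization-Free Pairwise Delta-Ct Screening of qPCR miRNA Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and locked-cutoff validation of circulating miRNA
    biomarkers from RT-qPCR threshold-cycle (Ct) matrices without reference
    normalizers. All unordered miRNA pairs are scored by the within-sample
    Ct difference ("diffpair"), which cancels per-sample global offsets;
    each pair is screened on a training cohort with Welch t-tests, rank-based
    ROC AUC, and a cutoff maximizing sensitivity plus specificity, gated at
    80/80, then the training-locked rules are applied unchanged to an
    independent test cohort and summarised as sensitivity, specificity, PPV
    and NPV with exact binomial confidence intervals. Includes two-sided
    Fisher exact tests for cohort demographics and a synthetic serum-qPCR
    cohort generator with planted effects, per-sample offsets, replicate
    reactions and right-censoring at the cycle limit.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
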