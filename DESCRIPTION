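Package: prsonset
Title: Clumping-and-Thresholding Polygenic Risk Scores for Depression Risk
    and Onset Timing in Alzheimer's Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construct clumping-and-thresholding (C+T) polygenic risk scores
    from GWAS summary statistics and evaluate them against depression case
    status and depression onset timing within an Alzheimer's disease cohort.
    Provides summary-statistic harmonization with allele flipping, APOE-region
    masking, greedy LD clumping, a p-value threshold sweep, two score
    formulas (standard weighted-sum and an interpretable risk-increasing
    average-of-risk-alleles score), logistic and ROC/AUC evaluation with a
    DeLong test for nested models, genotype PCA adjustment, and
    left-truncated right-censored time-to-event analysis with delayed-entry
    Kaplan-Meier curves and log-rank tests. Includes a synthetic-cohort
    generator (LD-blocked dosages, liability-threshold phenotypes,
    proportional-hazards onset ages under delayed entry) so the whole
    pipeline is testable without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
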