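Package: snpforest
Title: Random-Forest SNP Screening and Risk Prediction for Case-Control GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide random-forest pipeline for predicting a binary
    clinical outcome (severe asthma exacerbation) from SNP genotypes and
    clinical covariates. Implements two-stage chunked variable-importance
    screening of SNPs, top-k SNP plus clinical-trait forest models scored by
    tree vote fractions, permutation and random-SNP null controls,
    control-frequency imputation of missing genotypes, rank-statistic ROC/AUC
    evaluation with significance against chance, and a synthetic two-stage
    case-control GWAS cohort generator so the whole analysis runs and is
    tested at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    randomForest,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
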