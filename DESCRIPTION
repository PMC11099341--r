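Package: methylcrp
Title: Epigenome-Wide Analysis and DNA-Methylation Prediction of Chronic
    Inflammation (C-Reactive Protein)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying blood DNA-methylation signatures of chronic
    low-grade inflammation indexed by C-reactive protein (CRP). Provides a
    synthetic-cohort generator with known architecture (correlated CpG
    blocks, genetic and methylation-linked variance components, confounding,
    multi-wave longitudinal CRP with assay-sensitivity rules), CRP and
    genotype preprocessing, mass-univariate EWAS with inflation and
    attenuation diagnostics, a spike-plus-Gaussian-mixture Bayesian
    regression (Gibbs sampler) with posterior inclusion probabilities,
    probe grouping and variance partitioning, omics/genomic relationship
    matrices with AI-REML variance components, five styles of DNA-methylation
    CRP predictor (elastic net, Bayesian posterior-mean weights, PCA plus
    elastic net, EWAS-weight scores) with missing-probe projection, and an
    evaluation battery (correlations, incremental R-squared, ICC(2,k),
    longitudinal mixed models, linear/logistic/Cox outcome associations with
    FDR control, polygenic scoring).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    lme4,
    lmerTest,
    Rcpp,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
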