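Package: growthgwas
Title: Single-Step Nonlinear Mixed Model GWAS for Growth Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Longitudinal genome-wide association analysis in which SNP
    effects are embedded directly in the fixed effects of a nonlinear
    growth curve. Provides five classical growth-curve families (logistic,
    Gompertz, Brody, Von Bertalanffy, Richards) with AIC/BIC model
    selection; a nonlinear mixed model with bivariate individual
    deviations on mature weight (A) and maturity rate (K) fitted by
    maximum likelihood via a first-order conditional linearization, with
    an adaptive Gauss-Hermite quadrature oracle for validation;
    per-SNP likelihood-ratio scans (effects on A, K, or both) with
    Storey q-value or Benjamini-Hochberg FDR control; phenotype and
    genotype quality control (3-SD outliers, consecutive-decrease rule,
    call-rate/MAF/Hardy-Weinberg filters, LD pruning, PCA covariates);
    clustering of significant SNPs into QTL intervals with gene
    annotation; and a synthetic-cohort simulator matching the model's
    assumed data-generating process.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    MASS,
    minpack.lm,
    pracma,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0), jsonlite, nlme
Config/testthat/edition: 3
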