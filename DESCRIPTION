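Package: gweisr
Title: Genome-Wide Gene-Environment Interaction Scans with Robust
    Inference and Interaction-Based Polygenic Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Per-SNP gene-environment interaction regression (GWEIS) with
    Huber-White heteroscedasticity-robust standard errors and
    covariate-by-SNP / covariate-by-environment confounder control, plus a
    main-effect GWAS mode. Includes PLINK .bed/.bim/.fam input and output,
    genotype quality-control filtering, greedy LD clumping, genomic
    inflation diagnostics, layered Bonferroni threshold arithmetic,
    construction and hold-out evaluation of main-effect and
    interaction-based polygenic scores, phenotype and environment scoring
    rules for questionnaire sum scores, and a synthetic cohort generator
    (genotypes in Hardy-Weinberg equilibrium with block LD, typed
    environments, covariates, and phenotypes from the full interaction
    model) so that every stage of the pipeline can be exercised and
    calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
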