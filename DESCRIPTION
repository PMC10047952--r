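Package: deepgwas
Title: Image-Derived Endophenotypes from 3D Convolutional Networks for
    Genome-Wide Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An imaging-genetics analysis pipeline for structural brain
    MRI: data-driven feature extraction with 3D convolutional neural
    network classifiers of diagnostic status (whole-brain and
    multi-branch overlapping-patch variants, trained from scratch with
    bundled C++ kernels), reduction of the 100-unit penultimate-layer
    activations to principal-component endophenotypes, and per-SNP
    covariate-adjusted linear-regression association scans with genomic
    inflation diagnostics and PLINK-dialect summary statistics. Includes
    a synthetic-cohort generator (ellipsoid brain phantoms with planted
    class- and genotype-dependent localized atrophy, Hardy-Weinberg
    genotypes, covariates) so every stage is testable without restricted
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    glmnet,
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
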