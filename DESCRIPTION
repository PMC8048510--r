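Package: mttwas
Title: Multi-Tissue Transcriptome-Wide Association Studies with
    Multi-Task Expression Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two-stage transcriptome-wide association studies
    (TWAS) that borrow information across tissues when imputing
    genetically regulated gene expression.  Implements single-task
    expression predictors (lasso, ridge, elastic net, random forest) and
    their multi-task counterparts (an L2-fusion joint lasso solved by
    coordinate descent, and a stacked-design multi-task random forest
    with a tissue identifier available at every split); association
    testing of imputed expression by linear regression or a
    Mantel-stratified Cochran-Armitage trend test with
    Benjamini-Hochberg adjustment over all fitted models; a
    colocalisation filter that tests proportionality of principal
    component regression coefficients between the eQTL and GWAS signals;
    and a seedable simulation harness (LD-structured haplotype pools,
    causal-scenario trait generation) for measuring power and type-I
    error of the complete pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    ranger,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    yaml,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
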