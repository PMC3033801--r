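Package: pathfpc
Title: Pathway Association Testing in GWAS via Reduced Gene Subsets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pathway-based case-control association testing for genome-wide
    association studies. Each gene is summarized by the first principal
    component of its centered SNP dosages; a reduced gene subset is selected
    by LASSO-penalized logistic regression with AIC or BIC; pathway
    significance comes from a likelihood-ratio statistic with a
    size-constrained phenotype-permutation null, and multiple pathways are
    adjusted by permutation-based FDR and FWER on normalized statistics.
    Includes comparison statistics (most-significant SNP, rank truncated
    product, Fisher combination, admixture maximum likelihood), a
    case-control genotype simulator under a multiplicative relative-risk
    model, evaluation utilities (power, type I error, positive selection
    rate, McNemar), PED/MAP and GMT readers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
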