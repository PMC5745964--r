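Package: svdbayesc
Title: Direct SVD-Based BayesC Variable Selection for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genomic prediction from whole-genome sequence or SNP-chip
    genotypes using singular value decomposition of the standardized
    genotype matrix. Implements SNP-BLUP (ridge regression) in SVD
    component space with per-SNP prediction error variances, a direct,
    non-iterative BayesC approximation that converts prediction error
    variances into per-SNP posterior probabilities of a non-zero effect
    and variance weights, a reference single-site Gibbs BayesC sampler
    for cross-checking, a forward-in-time Wright-Fisher whole-genome
    simulator with recombination and infinite-sites mutation, and
    accuracy/bias evaluation over descendant generations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    GenomicRanges,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    SummarizedExperiment,
    utils,
    VariantAnnotation
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
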