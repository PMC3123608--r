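Package: capl
Title: Combined Family and Case-Control Association Testing with
    Population Stratification Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the combined APL (CAPL) test for genetic
    association, which integrates nuclear families and unrelated
    cases/controls in one statistic by treating singletons as one-sib
    families with missing parents. Population substructure is handled by
    Ward clustering of an identity-by-state distance matrix; per-marker
    EM estimates subpopulation allele frequencies, affected-sib-pair IBD
    sharing parameters and family probabilities of origin while
    integrating over missing parental mating types. The statistic
    compares observed counted-allele copies in affected siblings with
    their expectation conditional on (possibly inferred) parental
    genotypes; its variance is estimated by a bootstrap that re-clusters
    and re-runs the EM in every replicate. Includes PLINK text/binary
    readers, a deterministic per-marker parallel pipeline, and a
    synthetic-data generator for stratified pedigree designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    parallel,
    data.table,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
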