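Package: finepanel
Title: SNP Panel Selection and Evaluation for Fine-Scale Population Assignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates reduced SNP panels for genetic stock
    identification at fine spatial scales. Genotype matrices (Genepop or
    dosage TSV) are filtered on minor allele frequency, missingness and
    linkage-disequilibrium/FST redundancy; loci are ranked by Weir-Cockerham
    FST and by random-forest permutation importance (plain, regularized and
    guided-regularized variants, implemented from scratch with sequential
    feature-set accumulation); panels of matched sizes are scored by
    leave-one-out self-assignment accuracy under a training/holdout design
    with a baseline built from all individuals. A Balding-Nichols synthetic
    genotype generator reproduces the low-differentiation, sparse-missingness
    structure the workflow assumes, so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
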