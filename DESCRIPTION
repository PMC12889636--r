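Package: drivescan
Title: Detection of Sex-Ratio Segregation Distorters in Large Pedigrees
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genotype-free detection of sex-chromosome segregation distorters
    (meiotic drivers) in large multi-generation pedigrees, using only the
    recorded sexes of individuals. Provides a Bayesian-network carrier scorer
    that propagates distorter-carrier beliefs up and down a pedigree by
    sum-product message passing, whole-pedigree sex-permutation significance
    tests with three family-wise empirical p-value definitions, graph-based
    clustering of high-likelihood carriers into putative distorter families,
    patrilineal (Y-chromosome) lineage extraction with per-lineage
    transmission disequilibrium tests, Benjamini-Hochberg false discovery
    rate correction and binomial confidence envelopes, Monte Carlo family
    tests, and a seeded forward simulator of pedigrees with optionally
    planted distorters for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
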