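Package: divscape
Title: Genomic Divergence, Gene Flow and Outlier Detection Across
    Geographic Mosaics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing genomic divergence among populations
    arranged in a geographic mosaic, designed for low-coverage
    reduced-representation sequencing of non-model organisms.  Implements
    Bayesian population allele-frequency estimation that propagates
    per-individual genotype uncertainty, a hierarchical Bayesian F-model
    with posterior-predictive F_ST outlier calling, Burrows' composite
    measure of Hardy-Weinberg and linkage disequilibrium, approximate
    Bayesian computation of gene flow under isolation with migration,
    Mantel and partial Mantel matrix-correlation tests, allele-frequency
    cline regression, behavioural isolation indices, and a forward
    Wright-Fisher landscape simulator with host-associated, contact-zone
    and climate-clinal locus classes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    vcfR,
    yaml,
    geosphere,
    ggplot2
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
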