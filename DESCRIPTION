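Package: hzshift
Title: Temporal Hybrid-Zone Movement and Introgression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the movement of an avian hybrid zone
    between two sampling periods from biallelic SNP genotypes: ancestry
    estimation (maximum-likelihood hybrid index, K = 2 EM admixture,
    verification PCA), transect projection and sigmoid geographic cline
    fitting with bootstrap confidence intervals, per-locus Bayesian genomic
    clines (alpha/beta introgression outliers) fitted by Metropolis MCMC,
    chromosome-level outlier composition tests and consecutive-outlier run
    detection with a permutation null, and regional climate-change-rate
    contrasts from yearly raster stacks. Includes a synthetic-data generator
    that emulates a two-species contact-zone transect resampled across
    decades, so every stage has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    vcfR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
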