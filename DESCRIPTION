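Package: jaycline
Title: Geographic Cline Analysis of a Mito-Nuclear Avian Hybrid Zone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing secondary contact between divergent bird
    lineages along a one-dimensional transect. Provides a synthetic
    secondary-contact zone simulator with known truth, an in-silico
    restriction-digest assay for mtDNA haplotype typing, genotype quality
    control (Hardy-Weinberg and linkage-disequilibrium permutation tests
    with Bonferroni correction), a Bayesian admixture model for multiallelic
    microsatellites yielding per-individual ancestry (Q) scores, maximum
    likelihood fitting of sigmoid geographic clines with exponential tails
    by Metropolis-Hastings sampling with AICc model selection and
    two-log-likelihood support intervals, time-since-contact estimation
    under neutral diffusion, and regression of phenotypic traits on hybrid
    ancestry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    rlang,
    yaml,
    geosphere,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr,
    ggplot2
Config/testthat/edition: 3
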