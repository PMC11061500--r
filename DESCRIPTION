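Package: hybridrf
Title: Random-Forest Approximate Bayesian Computation for Hybrid Origin Inference from SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers the demographic history of homoploid hybrid lineages from
    reduced-representation SNP panels. Provides a DArT-style biallelic genotype
    container with the standard locus/individual filtering cascade
    (reproducibility, call rate, monomorphic removal, secondary-SNP thinning,
    group-polymorphism and minor-allele-frequency filters), a structured
    coalescent simulator for unlinked SNP loci under competing demographic
    scenarios with admixture, admixture-informative summary statistics (expected
    heterozygosity, Hudson FST, Nei distance, f3/f4), random-forest ABC model
    choice with vote fractions and out-of-bag posterior-probability estimation,
    quantile-regression-forest parameter estimation, pseudo-observed-dataset
    calibration, and a chloroplast-haplotype classifier for the maternal
    direction of hybridization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    ranger,
    MASS,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
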