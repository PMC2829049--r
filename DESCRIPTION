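Package: radscan
Title: Genotype Calling and Kernel-Smoothed Genome Scans for RAD-Seq
    Population Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Maximum-likelihood diploid genotype calling from per-site
    nucleotide read counts under a multinomial sequencing-error model with a
    per-site error rate, per-site population-genetic statistics (nucleotide
    diversity, observed heterozygosity, sample-size-weighted FST, private
    alleles, G-tests with Benjamini-Hochberg correction), Gaussian
    kernel-smoothed genome scans with bootstrap significance and delineation
    of candidate regions of selection, and a synthetic read-count simulator
    emulating replicate oceanic/freshwater population designs with parallel
    and non-parallel selective sweeps and balancing selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vctrs
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
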