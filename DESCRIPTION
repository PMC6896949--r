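Package: invmix
Title: Admixture, Founder and Diversity Inference for Clonal Plant Invasions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetics toolkit for reconstructing the demographic
    history of a single-introduction plant invasion from polyploid
    microsatellite genotypes and chloroplast haplotypes. Provides clonal
    (multilocus-genotype) filtering and clonal diversity, per-population and
    per-group diversity statistics (effective alleles, Shannon index,
    heterozygosities, fixation index, private alleles), haplotype diversity
    and nucleotide diversity with a Gst/Nst permutation test for
    phylogeographic structure, a three-source admixture-contribution
    likelihood maximised by grid search, an approximate Bayesian computation
    scan for the founding sample size, Shannon-index rarefaction with a
    saturation-curve fit, and growth-rate estimation on Bayesian-skyline
    point series. A synthetic-data generator (diverged sources, admixed
    founders, Wright-Fisher drift, clonal duplication, haplotype alignments)
    makes every stage testable without restricted field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
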