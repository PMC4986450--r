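Package: cnvadmix
Title: Admixture and Population Structure Analysis from Copy Number Variable Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for population-genetic analysis of
    copy number variation in admixed populations. Filters per-sample CNV
    segment calls with array-caller quality rules, merges them into copy
    number variable regions (CNVRs) with a cohort sample-frequency
    threshold, recodes integer copy-number states to biallelic genotypes,
    and analyses population structure via supervised random-forest
    proximity with classical multidimensional scaling, maximum-likelihood
    (EM) admixture estimation of individual ancestry proportions,
    multi-allelic Weir-Cockerham F_ST, ancestry-informative CNVR
    classification, and hypergeometric gene-set enrichment. Ships a
    synthetic-data generator (Balding-Nichols differentiated ancestral
    populations plus Dirichlet-admixed individuals, with probe-level
    segment emission) so the whole pipeline is testable end to end with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    GenomicRanges,
    IRanges,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
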