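Package: rohscan
Title: Runs of Homozygosity and Heterozygosity Analysis for SNP-Array Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) and heterozygosity (ROHet) in
    diploid SNP-chip genotypes with the consecutive scanning method, and builds
    the downstream population-genetic analyses that use them: genomic
    inbreeding coefficients (F_HOM and F_ROH, with per-length-class
    decomposition and generation dating from run length), outgroup-polarized
    genetic load from variant annotations, enrichment of damaging homozygotes
    inside ROH length classes, ROH/ROHet hotspot (island) detection by
    incidence percentiles with candidate-gene windows, and windowed Tajima's D
    and a beta-style balancing-selection scan. A pedigree gene-dropping
    simulator with exact identity-by-descent tracking supplies ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
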