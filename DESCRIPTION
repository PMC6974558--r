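Package: apiculate
Title: Population Genetics and Hybrid Genome Profiling for Apiculate Yeasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying Hanseniaspora (apiculate yeast) populations and
    their interspecific hybrids. Implements multi-locus sequence typing (MLST)
    diversity statistics with IUPAC-coded heterozygous sites, Weir-Cockerham
    inbreeding coefficients and selfing-rate estimation from multilocus
    heterozygosity profiles, two-parent subgenome profiling of hybrid genomes
    (competitive read assignment, windowed copy number, loss-of-heterozygosity
    detection, allele-balance ploidy diagnostics, identity-by-state distances,
    SNP PCA), flow-cytometry DNA-content ploidy calls, and a synthetic-data
    generator with known ground truth for every analysis stage. All user-facing
    functions take data frames and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    readr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
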