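Package: ldsv
Title: Structural Variation Detection from Short-Range Linkage Disequilibrium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate structural variations in SNP-array data from
    deviations of short-range linkage disequilibrium (LD). From phased
    haplotype panels the package computes pairwise r-squared within a 100 kb
    window, builds distance-binned expected-LD profiles per chromosome,
    tests each SNP for consistent deviation of its right-window neighbours
    from expectation (one-sample t-test with Benjamini-Hochberg FDR
    control), and calls structural variants as runs of at least three
    adjacent significant SNPs spanning at least 1 kb. Includes marker QC
    (missing rate, exact Hardy-Weinberg test, minor allele frequency),
    cross-population region merging, overlap counting against external
    interval sets, gene annotation, summary statistics, PCA of
    per-chromosome variant counts, and a seeded haplotype simulator with
    plantable high- and low-LD segments for validation.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    vcfR
Suggests:
    IRanges,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
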