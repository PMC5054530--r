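Package: xselscan
Title: Sex-Aware X-Chromosome Selection Scans with a Coalescent Drift Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for X-linked selection scans in structured populations with
    mixed sexes. Reads X-chromosome SNPs from VCF together with a sample sheet
    carrying population, sex and altitude, applies standard post-calling
    variant filters, and computes hemizygosity-aware allele counts (two
    chromosomes per female, one per male). Provides windowed nucleotide
    diversity, per-SNP Hudson and Weir-Cockerham Fst, two-sided Fisher exact
    tests with FDR correction, top-quantile outlier calling, gene-level
    outlier-SNP densities and scan intersection. A compiled two-population
    split coalescent simulates neutral allele frequencies for a drift-versus-
    selection test on candidate regions, and phased haplotype panels support
    gender-corrected major-haplotype frequencies, altitude clines tested by
    correlation, and pairwise linkage disequilibrium. A synthetic-study
    generator emulating populations along an altitude gradient makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
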