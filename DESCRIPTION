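Package: urbanflow
Title: Landscape Genetics of Urban Mosquito Populations from Genome-Wide SNPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting fine-scale gene flow in urban insect
    populations from genome-wide SNP genotypes. Implements the full analysis
    chain used in city-scale landscape genetics of container-breeding
    mosquitoes: VCF-based genotype filtering (missingness, Hardy-Weinberg
    exact test, call rate, minor allele frequency, physical thinning),
    Loiselle kinship with sibship classification and maximum-likelihood
    relationship tests, individual (Rousset's a) and group (Nei's D) genetic
    distances, one-level AMOVA, network isolation metrics for ports, rivers
    and highways, ordinary kriging of a habitat index, Mantel and partial
    Mantel tests, distance-based redundancy analysis with forward selection
    by adjusted R-squared, and a spatially explicit forward-time simulator
    that screens landscape models for inflated Type I error under pure
    isolation by distance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    vegan,
    vcfR,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
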