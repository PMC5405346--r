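Package: GBSpanel
Title: Genotyping-by-Sequencing Analysis of Germplasm Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the genetic characterization of germplasm
    collections genotyped by reduced-representation sequencing (GBS).
    Provides threshold-based genotype calling from per-allele read
    depths, marker filtering on minor allele frequency, call rate and
    heterozygosity, merging of SNP catalogs discovered by independent
    reference-free pipelines, private-allele accounting standardized
    for missing data by score-matched downsampling, probabilistic PCA
    tolerant of missing genotypes, mixed-linear-model association
    scans with a genomic kinship matrix, and greedy allele-coverage
    core-collection selection. A synthetic-data module simulates
    structured, mostly-inbred collections with realistic read-depth
    and missingness regimes so every stage can be validated against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: SNP, Genetics, PopulationGenetics, GenomeWideAssociation,
    Sequencing
RoxygenNote: 7.3.3
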