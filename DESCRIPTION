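Package: rerrs
Title: Reduced-Representation Metagenome Profiling and Host-Genetic Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for restriction-enzyme reduced-representation sequencing
    (RE-RRS) of microbial communities such as the rumen microbiome.  Provides
    a synthetic-data generator (in silico PstI digestion, size selection,
    barcoded single-end reads over communities with a known genetic
    architecture), demultiplexing and quality trimming, reference-based
    profiling by seeded local alignment with lowest-common-ancestor taxonomic
    assignment, reference-free profiling from 65 bp cut-site tags,
    compositional normalisation with within-cohort adjustment, sample
    networks and PERMANOVA on Bray-Curtis distances, and estimation of the
    genomic heritability and repeatability of taxon abundances with a
    VanRaden genomic relationship matrix and an average-information REML
    animal model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    ape,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
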