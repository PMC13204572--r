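Package: breedvar
Title: Two-Stage Comparative Analysis of Coding Variation Across Sheep Breeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a two-stage comparative analysis of protein-altering
    coding variation in livestock breeds, developed around three Greek
    indigenous sheep breeds (Lesvos, Serres, Thrace). The discovery stage
    covers quality filtering of annotated variant tables (read depth and
    mapping quality thresholds), missense/indel prioritization, per-gene
    length-normalized variant densities (SNPs/kb, indels/kb), and pairwise plus
    three-way partitioning of variant and gene sets into shared and
    breed-exclusive cells. The validation stage covers genotype call-rate QC,
    per-breed allele-frequency estimation, an exact 2xc contingency test by
    complete enumeration with Benjamini-Hochberg FDR control, and a four-way
    classification of validated SNPs against their discovery-phase breed
    labels. A seeded synthetic-data generator emulates the statistical
    structure of the study inputs, and a generic hypergeometric
    over-representation test over user-supplied gene sets is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
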