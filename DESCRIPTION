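Package: heritpart
Title: Partitioning Heritability with Thresholded Genomic Relationship
    Matrices in Animal Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for partitioning the heritability of quantitative and
    categorical traits in populations that contain close relatives, such as
    wild pedigreed vertebrate study systems.  Builds identity-by-state
    genomic relationship matrices (GRMs) from SNP genotypes, derives
    relatedness-thresholded, minor-allele-frequency-restricted and
    region-restricted GRMs, and constructs the pedigree numerator
    relationship matrix.  Fits multi-component animal models by average
    information restricted maximum likelihood (AI-REML) with repeated
    measures, estimates the population-level and kinship-associated
    heritability components and their sum, and compares nested models with
    likelihood-ratio tests.  Includes a synthetic wild-pedigree data
    generator (promiscuous mating, gene dropping, polygenic and monogenic
    trait architectures) so that every stage of the pipeline can be
    exercised and validated without external data.  Reads and writes PLINK
    bed/bim/fam genotypes and the GCTA binary GRM format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
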