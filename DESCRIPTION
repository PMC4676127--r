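Package: divscan
Title: Genome Diversity, Demography and Duplication Scanning for Small
    Resequencing Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for small multi-individual whole-genome
    resequencing studies of genetically depleted populations. Implements a
    windowed diversity battery (SNV rates, density windows,
    heterozygous/homozygous window classification, PLINK-style runs of
    homozygosity, tandem-repeat classification), a read-depth segmental
    duplication caller with iterative control-region normalisation, joint
    allele-frequency-spectrum demographic inference for two populations
    under four bottleneck/split models by Poisson composite likelihood,
    branch-specific Dn/Ds estimation by Nei-Gojobori counting on
    parsimony-reconstructed ancestors with bootstrap and permutation
    tests, and Hscore-weighted similarity-graph clustering of genes into
    families. A synthetic-data module generates coalescent cohorts, depth
    tracks, codon alignments and bit-score graphs with known truth so
    that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    Rcpp,
    Biostrings,
    IRanges,
    ape,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
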