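Package: parscan
Title: Scanning Pseudoautosomal Regions for Sexually Antagonistic Selection
Version: 0.1.0
Authors@R:
    person("parscan", "developers", email = "parscan@example.org",
           role = c("aut", "cre"))
Description: Tools to search young sex chromosomes for signatures of
    sexually antagonistic selection. Implements trio-based phasing of
    paternal X and Y haplotypes from pedigree-cross VCFs, windowed
    population-genetic statistics (Hudson's FST, nucleotide diversity,
    between-group divergence, Tajima's D, read-depth ratios, gene-tree
    consistency and Nei-Gojobori dN/dS), a permutation null with Storey
    q-value FDR control for outlier windows in the pseudoautosomal
    region, and a two-deme structured-coalescent simulator with a
    Y-linked sweep and demographic epochs used to calibrate a
    familywise critical p-value. A synthetic pedigree-cross generator
    with recorded truth makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    ape,
    VariantAnnotation,
    SummarizedExperiment,
    IRanges,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    rtracklayer,
    GenomicRanges
LinkingTo: Rcpp
Config/testthat/edition: 3
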