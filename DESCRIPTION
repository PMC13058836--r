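Package: abeGenotyper
Title: Amplicon NGS Genotyping of Adenine Base-Edited Cell Clones
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: High-throughput genotyping of cell clones modified with an
    adenine base editor (ABE), from targeted amplicon deep sequencing.
    Provides guide/protospacer geometry and codon synonymy annotation, a
    seeded paired-end amplicon read simulator with haplotype mixtures, a
    banded semi-global aligner with fragment-level pileup reconciliation,
    per-position allele-frequency matrices across clone cohorts, editing
    efficiency and mosaicism/zygosity classification, read-backed phasing
    of an induced substitution against a germline heterozygous variant
    with monoclonality assessment, and a Sanger-versus-NGS genotyping
    cost model with crossover computation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse,
    withr,
    knitr
biocViews: Sequencing, CRISPR, Alignment, GeneticVariability, Coverage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'abeGenotyper-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'align-quantify.R'
    'reference-model.R'
    'auts2-locus.R'
    'classify.R'
    'io.R'
    'phasing.R'
    'readsim.R'
    'report-cost.R'
    'show-methods.R'
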