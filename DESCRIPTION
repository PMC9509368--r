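Package: silkpan
Title: Pan-Genome Population Analysis Toolkit for Silkworm Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Window-based selective-sweep scanning (nucleotide diversity,
    Tajima's D, Hudson/Weir-Cockerham FST and a cross-population composite
    likelihood ratio score) with percentile-intersection sweep calling;
    pan-gene occupancy classification (core/softcore/dispensable/private),
    accumulation curves and exponential plateau modelling; construction,
    filtering, annotation and group-divergence scanning of non-redundant
    structural variants; and presence/absence association of structural
    variants with tissue expression. Includes seed-deterministic synthetic
    cohort generators (Balding-Nichols allele-frequency model with hard-sweep
    injection, occupancy matrices with prescribed class counts, SV cohorts
    with group-shifted frequencies, and SV-linked expression) so every stage
    can be exercised end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    minpack.lm,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, PopulationGenetics, StructuralVariation,
    FunctionalGenomics, Software
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'stats-core.R'
    'popgen-scan.R'
    'xpclr.R'
    'sweep-caller.R'
    'pangene.R'
    'sv-toolkit.R'
    'sv-expression.R'
    'simulate.R'
    'io.R'
    'pipeline.R'
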