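Package: lofgof
Title: Classification of Loss- and Gain-of-Function Mutations from Genomic Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for analysing loss-of-function (LoF) versus
    gain-of-function (GoF) mutations collected from literature sentences.
    Mutation mentions are parsed with a deterministic grammar, protein-level
    substitutions are back-mapped onto genomic coordinates and codon-level
    alleles through transcript models, and six features (reference allele,
    substituted allele, mutation type, functional-impact score, subcellular
    location, protein domain) are assembled per mutation. Hypergeometric
    enrichment of annotations, transition/transversion and allele-pair
    proportion tests, and a balanced-resampling repeated cross-validation
    harness for three classifiers quantify the discriminative power of the
    features. A synthetic-data module generates toy genomes, multi-exon
    transcripts on both strands, annotation tables and class-conditional
    mutations with known generative parameters, so every stage can be
    verified end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    e1071,
    ranger,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    BiocGenerics,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
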