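Package: ContigForge
Title: Post-Processing, Annotation and Differential Analysis of De Novo
    Transcriptome Meta-Assemblies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for turning raw RNA-seq reads and multi-k-mer de Bruijn
    assembler outputs into a non-redundant, coverage-filtered reference
    contig set with gene models, per-library quantification, filtered and
    classified sequence variants, and Fisher-exact differential analyses
    between pooled library groups. Implements N-based read cleansing with
    mate propagation, digital (median k-mer coverage) read normalization,
    per-locus representative selection, antisense-chimera detection,
    greedy identity clustering at nucleotide and protein level with
    longest-ORF representative selection, overlap merging of contigs,
    exact-seed read mapping with reads-per-million filtering, pileup-based
    SNP/indel calling with a depth/allele-count/MAF filter chain, and a
    transcript-coordinate variant effect classifier. A deterministic
    synthetic-data generator with planted ground truth supports
    parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    VariantAnnotation,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, Sequencing, Alignment, SNP, Coverage,
    DifferentialExpression
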