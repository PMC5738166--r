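Package: lncunits
Title: Transcription-Unit Calling and Noncoding RNA Annotation from
    Binned Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Annotates the noncoding transcriptome of a compact fungal
    genome from strand-specific RNA-seq, RNA polymerase II ChIP-seq and
    polysome-fractionation coverage. The genome is segmented into fixed
    50 bp bins, a bin-level logistic classifier of transcription is
    fitted on RNA-seq and RNAPII covariates, and contiguous
    super-threshold bins are merged into transcription units. Units are
    classified into coding genes and long intergenic noncoding RNAs
    (lincRNAs) with a polysome-based coding filter, natural antisense
    transcripts are detected from per-strand fits, splice junctions are
    classified against annotated introns, light-induced features are
    called from a time course, and coordinates are lifted between
    assembly versions related by reverse complementation. A synthetic
    data generator with planted truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
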