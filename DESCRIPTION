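Package: tefamquant
Title: Family-Level Quantification of Transposable Element Expression
    from RNA-Seq Alignments
Version: 0.9.0
Authors@R:
    person("tefamquant", "developers", email = "tefamquant@users.noreply.github.com",
           role = c("aut", "cre"))
Description: Quantifies transcript abundance of transposable element (TE)
    families from short-read RNA-seq alignments in repetitive genomes.
    Reads are classified against a merged, disjoined, exon-masked gene/TE
    annotation into unique and multi-mapping categories (family-unique,
    family-multi, and gene/TE-ambiguous), so that multi-mapped reads whose
    hits all fall within one TE family are retained instead of discarded.
    Downstream layers provide reads-per-million normalization, expressed-
    feature calling, the tau tissue-specificity index, Hartigan's dip test
    with Monte-Carlo p-values for expression segregation in recombinant
    inbred lines, a negative-binomial differential-expression test with
    Benjamini-Hochberg correction, and mid-parent additivity classification
    for hybrid trios.  A synthetic-data generator emits annotations and SAM
    alignments with exact ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
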