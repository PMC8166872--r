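Package: dirtseq
Title: Detection of Dicistronic tRNA-mRNA Transcripts from RNA-seq Alignments
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the DiRT (Dicistronic RNA Transcripts) detection
    procedure for identifying putative dicistronic tRNA-mRNA transcripts from
    short-read RNA-seq alignments against any annotated genome. The pipeline
    assembles adjacent tRNA/protein-coding gene pairs from GFF3 and BED
    annotations, applies expression filters, contrasts per-base intergenic
    coverage against the two introns closest to the intergenic gap with
    replicate-level t-tests and Benjamini-Hochberg FDR control, and requires
    continuous read coverage across the intergenic region. A format-faithful
    simulator of aligned reads with planted dicistronic loci, expression
    summaries (CPM/logCPM, component correlations), candidate-table
    summarization and a command-line interface are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    IRanges,
    S4Vectors,
    GenomicRanges,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
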