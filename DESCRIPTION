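Package: readscape
Title: Nucleotide-Resolution Distribution of Aligned Reads Across Genomic
    Categories and Biotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment quality control for any NGS experiment: flattens a
    GTF annotation into reusable non-overlapping stranded and unstranded
    indexes mapping every genomic position to its category-biotype annotation
    at each hierarchy level (gene, exon/intron, CDS/UTR, start/stop codon),
    intersects per-strand read coverage from BAM or bedgraph input with those
    indexes at nucleotide resolution, and reports raw and genome-size
    normalized (enrichment) distributions per category and per gene biotype,
    with grouped bar plots for multi-sample comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    parallel,
    IRanges,
    S4Vectors,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    ggplot2,
    patchwork
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
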