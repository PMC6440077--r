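# position-wise comparison helper: label set of the index at one position
indexAnnotAt <- function(tab, chrom, pos, strand = NULL) {
    hit <- tab$chrom == chrom & tab$start <= pos & tab$end > pos
    if (!is.null(strand)) hit <- hit & tab$strand == strand
    if (!any(hit)) return(character())
    sort(unique(unlist(strsplit(tab$annot[hit], ";", fixed = TRUE))))
}

test_that("a single gene flattens into the expected UTR/CDS/codon tiling", {
    recs <- parseGtf(toyGtfPath())
    flat <- flattenGene(recs)
    expect_equal(flat$start, c(10L, 15L, 18L, 30L))
    expect_equal(flat$end, c(15L, 18L, 30L, 40L))
    expect_equal(flat$annot, c(
        "protein_coding|exon|five_prime_utr|",
        "protein_coding|exon|CDS|start_codon",
        "protein_coding|exon|CDS|",
        "protein_coding|exon|three_prime_utr|"))
})

test_that("a gene without exon records is a single undescribed_gene span", {
    gtf <- withr::local_tempfile(fileext = ".gtf")
    writeLines(paste0("chr1\tsrc\tgene\t11\t40\t.\t+\t.\t",
                      "gene_id \"G1\"; gene_biotype \"lincRNA\";"), gtf)
    flat <- flattenGene(parseGtf(gtf))
    expect_equal(nrow(flat), 1L)
    expect_equal(flat$start, 10L)
    expect_equal(flat$end, 40L)
    expect_equal(flat$annot, "lincRNA|undescribed_gene||")
})

test_that("disagreeing transcripts keep both labels (positional ambiguity)", {
    gtf <- withr::local_tempfile(fileext = ".gtf")
    writeLines(c(
        paste0("chr1\tsrc\tgene\t11\t40\t.\t+\t.\t",
               "gene_id \"G1\"; gene_biotype \"protein_coding\";"),
        paste0("chr1\tsrc\texon\t11\t40\t.\t+\t.\t",
               "gene_id \"G1\"; transcript_id \"t1\";",
               " gene_biotype \"protein_coding\";"),
        paste0("chr1\tsrc\tCDS\t11\t30\t.\t+\t.\t",
               "gene_id \"G1\"; transcript_id \"t1\";",
               " gene_biotype \"protein_coding\";"),
        paste0("chr1\tsrc\texon\t11\t40\t.\t+\t.\t",
               "gene_id \"G1\"; transcript_id \"t2\";",
               " gene_biotype \"protein_coding\";"),
        paste0("chr1\tsrc\tthree_prime_utr\t21\t40\t.\t+\t.\t",
               "gene_id \"G1\"; transcript_id \"t2\";",
               " gene_biotype \"protein_coding\";")), gtf)
    flat <- flattenGene(parseGtf(gtf))
    # position 25 (0-based) is CDS in t1 and 3'UTR in t2
    hit <- flat$start <= 25 & flat$end > 25
    expect_equal(flat$annot[hit],
                 "protein_coding|exon|CDS,three_prime_utr|")
})

test_that("children outside the gene record extend the span with a warning", {
    gtf <- withr::local_tempfile(fileext = ".gtf")
    writeLines(c(
        paste0("chr1\tsrc\tgene\t11\t40\t.\t+\t.\t",
               "gene_id \"G1\"; gene_biotype \"miRNA\";"),
        paste0("chr1\tsrc\texon\t11\t50\t.\t+\t.\t",
               "gene_id \"G1\"; gene_biotype \"miRNA\";")), gtf)
    expect_warning(flat <- flattenGene(parseGtf(gtf)),
                   "outside the gene record span")
    expect_equal(max(flat$end), 50L)
})

test_that("bare 'UTR' features are assigned 5'/3' by position vs the CDS", {
    for (strand in c("+", "-")) {
        spec <- toyGeneSpec()
        tx <- spec$genes[[1]]$transcripts[[1]]
        tx$bareUtr <- c(tx$utr5, tx$utr3)
        tx$utr5 <- list(); tx$utr3 <- list()
        spec$genes[[1]]$transcripts[[1]] <- tx
        spec$genes[[1]]$strand <- strand
        flat <- flattenGene(parseGtf(toyGtfPath(spec)))
        left <- indexAnnotAt(flat, "chr1", 12)   # upstream of CDS 16-30
        right <- indexAnnotAt(flat, "chr1", 35)  # downstream of CDS
        if (strand == "+") {
            expect_match(left, "five_prime_utr")
            expect_match(right, "three_prime_utr")
        } else {
            expect_match(left, "three_prime_utr")
            expect_match(right, "five_prime_utr")
        }
    }
})

test_that("same-strand gene overlap deduplicates identical annotations but
           keeps differing biotypes as ambiguity", {
    gtf <- withr::local_tempfile(fileext = ".gtf")
    lines <- function(id, bt, from, to) c(
        paste0("chr1\tsrc\tgene\t", from, "\t", to, "\t.\t+\t.\t",
               "gene_id \"", id, "\"; gene_biotype \"", bt, "\";"),
        paste0("chr1\tsrc\texon\t", from, "\t", to, "\t.\t+\t.\t",
               "gene_id \"", id, "\"; gene_biotype \"", bt, "\";"))
    # identical category+biotype: stored once, not ambiguous
    writeLines(c(lines("A", "protein_coding", 11, 40),
                 lines("B", "protein_coding", 21, 30)), gtf)
    idx <- buildFeatureIndex(parseGtf(gtf))
    ann <- indexAnnotAt(strandedIndex(idx), "chr1", 25, "+")
    expect_length(ann, 1L)

    # differing biotypes: both kept -> ambiguous at every depth
    writeLines(c(lines("A", "protein_coding", 11, 40),
                 lines("B", "miRNA", 21, 30)), gtf)
    idx <- buildFeatureIndex(parseGtf(gtf))
    ann <- indexAnnotAt(strandedIndex(idx), "chr1", 25, "+")
    expect_length(ann, 2L)
})

test_that("unstranded annotation set is the union of the stranded sets", {
    for (seed in c(2L, 5L, 9L, 13L)) {
        spec <- randomToySpec(seed)
        idx <- suppressWarnings(
            buildFeatureIndex(parseGtf(toyGtfPath(spec))))
        str <- strandedIndex(idx)
        uns <- unstrandedIndex(idx)
        for (ch in names(spec$chromLengths)) {
            probe <- unique(c(str$start[str$chrom == ch],
                              str$end[str$chrom == ch] - 1L,
                              uns$start[uns$chrom == ch]))
            for (pos in probe) {
                expected <- sort(unique(c(
                    indexAnnotAt(str, ch, pos, "+"),
                    indexAnnotAt(str, ch, pos, "-"))))
                expect_identical(indexAnnotAt(uns, ch, pos), expected,
                                 label = sprintf("seed %d %s:%d", seed,
                                                 ch, pos))
            }
        }
    }
})

test_that("index intervals are disjoint and genome sizes conserve length", {
    for (seed in c(4L, 11L, 17L)) {
        spec <- randomToySpec(seed)
        idx <- suppressWarnings(indexGtf(toyGtfPath(spec)))
        for (variant in c("stranded", "unstranded")) {
            tab <- if (variant == "stranded") strandedIndex(idx) else
                unstrandedIndex(idx)
            for (k in unique(paste(tab$chrom, tab$strand))) {
                sub <- tab[paste(tab$chrom, tab$strand) == k, ]
                sub <- sub[order(sub$start), ]
                expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]) ||
                            nrow(sub) < 2)
            }
            # annotated chroms only: skip chroms with no features
            lens <- spec$chromLengths[names(spec$chromLengths) %in%
                                          unique(tab$chrom)]
            for (pol in c("discard", "split")) {
                sz <- genomeSizes(idx, 3, variant, chromLengths = lens,
                                  ambiguityPolicy = pol)
                mult <- if (variant == "stranded") 2 else 1
                expect_equal(attr(sz, "total"), mult * sum(lens),
                             tolerance = 1e-9)
                expect_equal(sum(sz$size) + attr(sz, "ambiguous"),
                             attr(sz, "total"), tolerance = 1e-9)
            }
        }
    }
})

test_that("toy genome sizes match the hand-derived values", {
    idx <- indexGtf(toyGtfPath())
    sz <- genomeSizes(idx, 3, "unstranded", chromLengths = c(chr1 = 100))
    got <- stats::setNames(sz$size, sz$category)
    expect_equal(got[["five_prime_utr"]], 5)
    expect_equal(got[["CDS"]], 15)  # includes the start codon nucleotides
    expect_equal(got[["three_prime_utr"]], 10)
    expect_equal(got[["intergenic"]], 70)

    szs <- genomeSizes(idx, 3, "stranded", chromLengths = c(chr1 = 100))
    gots <- stats::setNames(szs$size, szs$category)
    expect_equal(gots[["opposite_strand"]], 30)
    expect_equal(gots[["intergenic"]], 140)  # 70 per strand
    expect_equal(attr(szs, "total"), 200)
})

test_that("index round-trips through its files and detects corruption", {
    dir <- withr::local_tempdir()
    idx <- indexGtf(toyGtfPath(dir = dir))
    base <- file.path(dir, "toy")
    writeFeatureIndex(idx, base)
    back <- readFeatureIndex(base)
    expect_equal(strandedIndex(back), strandedIndex(idx))
    expect_equal(unstrandedIndex(back), unstrandedIndex(idx))
    expect_equal(back@sourceDigest, idx@sourceDigest)

    # partial read of only the unstranded variant
    part <- readFeatureIndex(base, variant = "unstranded")
    expect_equal(unstrandedIndex(part), unstrandedIndex(idx))
    expect_equal(nrow(strandedIndex(part)), 0L)

    # determinism: rebuilding and rewriting is byte-identical
    idx2 <- indexGtf(file.path(dir, "toy.gtf"))
    base2 <- file.path(dir, "again")
    writeFeatureIndex(idx2, base2)
    expect_identical(readLines(paste0(base, ".stranded.index.tsv")),
                     readLines(paste0(base2, ".stranded.index.tsv")))

    # corruption and version errors
    p <- paste0(base, ".stranded.index.tsv")
    lines <- readLines(p)
    lines[5] <- "chr1\toops"
    writeLines(lines, p)
    expect_error(readFeatureIndex(base, variant = "stranded"),
                 "line 5")
    lines[1] <- "# readscape feature index v99"
    writeLines(lines, p)
    expect_error(readFeatureIndex(base, variant = "stranded"),
                 "re-run indexing")
})

test_that("an empty record stream refuses to build an index", {
    expect_error(buildFeatureIndex(parseGtf(withr::local_tempfile(
        lines = "# empty", fileext = ".gtf"))), "no usable features")
})
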