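test_that("classifyPosition resolves depth, strand and virtual categories", {
    idx <- indexGtf(toyGtfPath())
    # 0-based position 16 sits in the start codon (16-18 1-based => [15,18))
    expect_equal(classifyPosition(idx, "chr1", 16, "+", "forward", 4),
                 data.frame(category = "start_codon",
                            biotype = "protein_coding"))
    expect_equal(classifyPosition(idx, "chr1", 16, "+", "forward", 3),
                 data.frame(category = "CDS", biotype = "protein_coding"))
    expect_equal(classifyPosition(idx, "chr1", 16, "+", "forward", 2),
                 data.frame(category = "exon", biotype = "protein_coding"))
    expect_equal(classifyPosition(idx, "chr1", 16, "+", "forward", 1),
                 data.frame(category = "gene", biotype = "protein_coding"))
    # an antisense read over the gene is opposite_strand
    expect_equal(classifyPosition(idx, "chr1", 20, "-", "forward", 3),
                 data.frame(category = "opposite_strand",
                            biotype = "opposite_strand"))
    # outside any gene on both strands
    expect_equal(classifyPosition(idx, "chr1", 60, "+", "forward", 3),
                 data.frame(category = "intergenic",
                            biotype = "intergenic"))
    # unstranded mode consults the union index
    expect_equal(classifyPosition(idx, "chr1", 35, strandMode =
                                      "unstranded", depth = 3)$category,
                 "three_prime_utr")
})

test_that("uniform coverage reproduces the genome size distribution", {
    spec <- toyGeneSpec()
    idx <- indexGtf(toyGtfPath(spec))
    fc <- suppressMessages(intersectCounts(uniformTrack(spec), idx, 3))
    ct <- countsTable(fc)
    expect_equal(stats::setNames(ct$count, ct$category),
                 c(intergenic = 70, CDS = 15, five_prime_utr = 5,
                   three_prime_utr = 10))
    expect_equal(ambiguousDiscarded(fc), 0)
    sz <- genomeSizes(idx, 3, "unstranded", chromLengths = c(chr1 = 100))
    expect_equal(ct$count, sz$size)
})

test_that("empty tracks and bad depths are handled", {
    idx <- indexGtf(toyGtfPath())
    empty <- new("CoverageTrack", sampleLabel = "e",
                 strandMode = "unstranded")
    fc <- intersectCounts(empty, idx, 3)
    expect_equal(nrow(countsTable(fc)), 0L)
    expect_equal(ambiguousDiscarded(fc), 0)
    expect_error(intersectCounts(empty, idx, 5), "depth")
})

test_that("ambiguous nucleotides are discarded or split equally", {
    gtf <- withr::local_tempfile(fileext = ".gtf")
    writeLines(c(
        paste0("chr1\tsrc\tgene\t11\t40\t.\t+\t.\t",
               "gene_id \"A\"; gene_biotype \"protein_coding\";"),
        paste0("chr1\tsrc\texon\t11\t40\t.\t+\t.\t",
               "gene_id \"A\"; transcript_id \"t1\";",
               " gene_biotype \"protein_coding\";"),
        paste0("chr1\tsrc\tCDS\t11\t40\t.\t+\t.\t",
               "gene_id \"A\"; transcript_id \"t1\";",
               " gene_biotype \"protein_coding\";"),
        paste0("chr1\tsrc\texon\t11\t40\t.\t+\t.\t",
               "gene_id \"A\"; transcript_id \"t2\";",
               " gene_biotype \"protein_coding\";"),
        paste0("chr1\tsrc\tthree_prime_utr\t11\t40\t.\t+\t.\t",
               "gene_id \"A\"; transcript_id \"t2\";",
               " gene_biotype \"protein_coding\";")), gtf)
    idx <- indexGtf(gtf)
    track <- makeTrack("chr1", 20, 30, depth = 1, lens = c(chr1 = 100))

    fc <- suppressMessages(intersectCounts(track, idx, 3, "discard"))
    expect_equal(ambiguousDiscarded(fc), 10)
    expect_equal(sum(countsTable(fc)$count), 0)

    fs <- suppressMessages(intersectCounts(track, idx, 3, "split"))
    expect_equal(ambiguousDiscarded(fs), 0)
    expect_equal(countOf(fs, "CDS"), 5)
    expect_equal(countOf(fs, "three_prime_utr"), 5)

    # the conflict is invisible below the reporting depth
    f2 <- suppressMessages(intersectCounts(track, idx, 2, "discard"))
    expect_equal(ambiguousDiscarded(f2), 0)
    expect_equal(countOf(f2, "exon"), 10)
})

test_that("chromosomes absent from the index are tallied, not counted", {
    idx <- indexGtf(toyGtfPath())
    track <- makeTrack(c("chr1", "chrUn"), c(0, 0), c(10, 50),
                       lens = c(chr1 = 100, chrUn = 200))
    expect_warning(fc <- suppressMessages(intersectCounts(track, idx, 3)),
                   "chrUn")
    expect_equal(unmatchedChromDiscarded(fc), 50)
    expect_conservation(fc, track)
})

test_that("batch counting is order-preserving and worker-invariant", {
    spec <- randomToySpec(12L)
    idx <- suppressWarnings(indexGtf(toyGtfPath(spec)))
    tracks <- lapply(1:3, function(k)
        readsToTrack(randomReads(spec, 200, seed = 100 + k),
                     spec$chromLengths, paste0("S", k), "forward"))
    serial <- suppressMessages(countSamples(tracks, idx, 3))
    par4 <- suppressMessages(countSamples(tracks, idx, 3, workers = 4))
    expect_equal(length(serial), 3L)
    for (k in 1:3) {
        expect_equal(sampleLabel(serial[[k]]), paste0("S", k))
        expect_counts_equal(serial[[k]], par4[[k]])
    }
    solo <- suppressMessages(intersectCounts(tracks[[1]], idx, 3))
    expect_counts_equal(serial[[1]], solo)
})

test_that("a failing sample aborts the batch with its label", {
    idx <- indexGtf(toyGtfPath())
    bad <- new("CoverageTrack", sampleLabel = "broken",
               strandMode = "forward")  # stranded track, empty ok...
    idxU <- readsToTrack(plannedReads("chr1", 0, 50, 20, seed = 2),
                         c(chr1 = 100L), "ok", "unstranded")
    # force failure: stranded-mode track against an index whose stranded
    # variant was not loaded
    dir <- withr::local_tempdir()
    writeFeatureIndex(idx, file.path(dir, "t"))
    part <- readFeatureIndex(file.path(dir, "t"), variant = "unstranded")
    str <- readsToTrack(plannedReads("chr1", 0, 50, 20, seed = 2),
                        c(chr1 = 100L), "broken", "forward")
    expect_error(suppressMessages(countSamples(list(idxU, str), part, 3)),
                 "broken")
})

test_that("the counts file includes zero rows and round-trips", {
    dir <- withr::local_tempdir()
    spec <- toyGeneSpec()
    idx <- indexGtf(toyGtfPath(spec))
    sz <- genomeSizes(idx, 3, "unstranded", chromLengths = c(chr1 = 100))
    # cover only the CDS: other pairs must still be written, with 0
    track <- makeTrack("chr1", 18, 30, depth = 2, lens = c(chr1 = 100))
    fc <- suppressMessages(intersectCounts(track, idx, 3))
    path <- file.path(dir, "counts.tsv")
    writeFeatureCounts(fc, sz, path)
    back <- readFeatureCounts(path)
    expect_equal(nrow(back), nrow(sz))
    expect_equal(back$nucleotide_count[back$category == "CDS"], 24)
    expect_equal(back$nucleotide_count[back$category == "intergenic"], 0)
    expect_equal(back$genome_size, sz$size)

    # a pair absent from the sizes is a hard error (depth mismatch):
    # cover the start codon so the depth-4 counts hold a depth-4 category
    sz4 <- genomeSizes(idx, 4, "unstranded", chromLengths = c(chr1 = 100))
    track4 <- makeTrack("chr1", 15, 30, depth = 1, lens = c(chr1 = 100))
    fc4 <- suppressMessages(intersectCounts(track4, idx, 4))
    expect_error(writeFeatureCounts(fc4, sz, path), "absent from")
    expect_silent(writeFeatureCounts(fc4, sz4, path))
})

test_that("depth-4 counts aggregate exactly to shallower depths", {
    # canonical toy gene: ambiguity-free by construction
    spec <- toyGeneSpec()
    idx <- indexGtf(toyGtfPath(spec))
    tr <- uniformTrack(spec)
    f4 <- suppressMessages(intersectCounts(tr, idx, 4))
    for (d in 1:3)
        expect_counts_equal(aggregateCounts(f4, d),
                            suppressMessages(intersectCounts(tr, idx, d)))

    for (seed in c(21L, 22L)) {
        spec <- randomToySpec(seed)
        idx <- suppressWarnings(indexGtf(toyGtfPath(spec)))
        tr <- readsToTrack(randomReads(spec, 300, seed = seed * 10),
                           spec$chromLengths, "s", "forward")
        f4 <- suppressMessages(intersectCounts(tr, idx, 4))
        if (ambiguousDiscarded(f4) > 0) next  # only ambiguity-free claims
        for (d in 1:3) {
            fd <- suppressMessages(intersectCounts(tr, idx, d))
            if (ambiguousDiscarded(fd) > 0) next
            agg <- aggregateCounts(f4, d)
            expect_counts_equal(agg, fd)
        }
    }
})

test_that("flipping every strand leaves the counts invariant", {
    spec <- randomToySpec(14L)
    # drop the bare-UTR dialect: its 5'/3' meaning is positional, so it is
    # the one annotation feature that legitimately changes under a world
    # flip; the symmetry claim is about explicit features
    spec$genes <- lapply(spec$genes, function(g) {
        g$transcripts <- lapply(g$transcripts, function(tx) {
            tx$bareUtr <- list()
            tx
        })
        g
    })
    flipped <- spec
    flipped$genes <- lapply(spec$genes, function(g) {
        g$strand <- c("+" = "-", "-" = "+", "." = ".")[[g$strand]]
        g
    })
    reads <- randomReads(spec, 300, seed = 140)
    readsFlip <- reads
    readsFlip$strand <- ifelse(reads$strand == "+", "-", "+")
    idx <- suppressWarnings(indexGtf(toyGtfPath(spec)))
    idxFlip <- suppressWarnings(indexGtf(toyGtfPath(flipped)))
    for (d in 1:4) {
        a <- suppressMessages(suppressWarnings(intersectCounts(
            readsToTrack(reads, spec$chromLengths, "s", "forward"),
            idx, d)))
        b <- suppressMessages(suppressWarnings(intersectCounts(
            readsToTrack(readsFlip, spec$chromLengths, "s", "forward"),
            idxFlip, d)))
        expect_counts_equal(a, b)
    }
})
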