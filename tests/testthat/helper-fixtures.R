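# shared fixtures: everything is generated in code at test time

toyGtfPath <- function(spec = toyGeneSpec(), dir = NULL) {
    if (is.null(dir)) {
        dir <- tempfile("fixture")
        dir.create(dir)
    }
    path <- file.path(dir, "toy.gtf")
    makeToyAnnotation(spec, path)
    path
}

# uniform depth-1 unstranded coverage over every chromosome of a spec
uniformTrack <- function(spec, label = "uniform") {
    lens <- spec$chromLengths
    iv <- data.frame(chrom = names(lens), start = 0L,
                     end = as.integer(lens), strand = ".", depth = 1,
                     stringsAsFactors = FALSE)
    new("CoverageTrack", sampleLabel = label, strandMode = "unstranded",
        intervals = iv[order(iv$chrom), , drop = FALSE],
        chromLengths = spec$chromLengths)
}

# single-interval track builder for hand-written cases
makeTrack <- function(chrom, start, end, depth = 1, strand = ".",
                      strandMode = "unstranded", lens = NULL,
                      label = "t") {
    iv <- data.frame(chrom = chrom, start = as.integer(start),
                     end = as.integer(end), strand = strand,
                     depth = as.numeric(depth), stringsAsFactors = FALSE)
    iv <- iv[order(iv$chrom, iv$strand, iv$start), , drop = FALSE]
    if (is.null(lens))
        lens <- vapply(split(iv$end, iv$chrom), max, numeric(1))
    new("CoverageTrack", sampleLabel = label, strandMode = strandMode,
        intervals = iv, chromLengths = stats::setNames(as.integer(lens),
                                                       names(lens)))
}

expect_counts_equal <- function(a, b, tolerance = 0) {
    ta <- countsTable(a)
    tb <- countsTable(b)
    expect_equal(ta$category, tb$category)
    expect_equal(ta$biotype, tb$biotype)
    if (tolerance == 0) {
        expect_identical(ta$count, tb$count)
        expect_identical(ambiguousDiscarded(a), ambiguousDiscarded(b))
    } else {
        expect_equal(ta$count, tb$count, tolerance = tolerance)
        expect_equal(ambiguousDiscarded(a), ambiguousDiscarded(b),
                     tolerance = tolerance)
    }
    expect_equal(unmatchedChromDiscarded(a), unmatchedChromDiscarded(b))
}

expect_conservation <- function(fc, track) {
    expect_equal(sum(countsTable(fc)$count) + ambiguousDiscarded(fc) +
                     unmatchedChromDiscarded(fc),
                 trackTotal(track), tolerance = 1e-9)
}

countOf <- function(fc, category, biotype = NULL) {
    ct <- countsTable(fc)
    hit <- ct$category == category
    if (!is.null(biotype)) hit <- hit & ct$biotype == biotype
    if (!any(hit)) return(0)
    sum(ct$count[hit])
}
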