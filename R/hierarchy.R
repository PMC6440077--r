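#' Aggregate counts upward through the category hierarchy
#'
#' Maps each category of a [FeatureCounts] to its ancestor at the target
#' depth (start/stop codons to CDS, CDS/UTRs/undescribed_exon to exon,
#' exon/intron/undescribed_gene to gene) and sums. On ambiguity-free data
#' this reproduces exactly what a run at the shallower depth would have
#' produced; with ambiguity the two can differ, because ambiguity is
#' evaluated at the reporting depth (labels that conflict at depth 4 may
#' agree at depth 2).
#'
#' @param counts a [FeatureCounts].
#' @param toDepth target depth, 1..4, at most the counts' depth.
#' @return A [FeatureCounts] at `toDepth`.
#' @export
aggregateCounts <- function(counts, toDepth) {
    stopifnot(is(counts, "FeatureCounts"))
    if (!toDepth %in% 1:4 || toDepth > counts@depth)
        stop("toDepth must be in 1..", counts@depth)
    lev <- categoryLevels()
    ct <- counts@counts
    cat <- ct$category
    repeat {
        deep <- lev[cat] > toDepth
        if (!any(deep)) break
        cat[deep] <- .CATEGORY_PARENT[cat[deep]]
    }
    key <- paste(cat, ct$biotype, sep = "\t")
    agg <- rowsum(ct$count, key)
    new("FeatureCounts",
        sampleLabel = counts@sampleLabel, depth = as.integer(toDepth),
        strandMode = counts@strandMode,
        ambiguityPolicy = counts@ambiguityPolicy,
        counts = .pairsToTable(stats::setNames(agg[, 1], rownames(agg)),
                               valueName = "count"),
        ambiguousDiscarded = counts@ambiguousDiscarded,
        unmatchedChromDiscarded = counts@unmatchedChromDiscarded,
        trackTotal = counts@trackTotal)
}
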