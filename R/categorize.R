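#' Classify a single genomic position
#'
#' Returns the category-biotype pairs annotating one nucleotide at the
#' chosen reporting depth. In unstranded mode the unstranded index is
#' consulted; in the stranded modes the read's assigned strand is looked up
#' in the stranded index, an unannotated position facing annotation on the
#' other strand is `opposite_strand`, and a position annotated on neither
#' strand is `intergenic`. A result with more than one row marks positional
#' ambiguity at this depth.
#'
#' This is the reference semantics of the package; [intersectCounts]
#' computes the same classification for whole coverage tracks by interval
#' splitting instead of per-position lookups.
#'
#' @param index a [FeatureIndex].
#' @param chrom chromosome name.
#' @param pos 0-based position.
#' @param strand assigned read strand, `"+"`/`"-"` (ignored in unstranded
#'   mode).
#' @param strandMode `"unstranded"`, `"forward"` or `"reverse"`; the mode
#'   only selects the index variant here — strand flipping for reverse
#'   libraries happens when coverage is computed.
#' @param depth reporting depth, 1..4.
#' @return data.frame with columns `category` and `biotype`.
#' @export
classifyPosition <- function(index, chrom, pos, strand = ".",
                             strandMode = c("unstranded", "forward",
                                            "reverse"),
                             depth = 3L) {
    stopifnot(is(index, "FeatureIndex"))
    strandMode <- match.arg(strandMode)
    if (!depth %in% 1:4) stop("depth must be in 1..4")
    if (strandMode == "unstranded") {
        tab <- index@unstranded
        hit <- tab$chrom == chrom & tab$start <= pos & tab$end > pos
        if (!any(hit))
            return(data.frame(category = "intergenic",
                              biotype = "intergenic",
                              stringsAsFactors = FALSE))
        return(.pairKeysToTable(.tokenPairsAtDepth(tab$annot[hit][1], depth)))
    }
    tab <- index@stranded
    hit <- tab$chrom == chrom & tab$strand == strand &
        tab$start <= pos & tab$end > pos
    if (any(hit))
        return(.pairKeysToTable(.tokenPairsAtDepth(tab$annot[hit][1], depth)))
    opp <- if (strand == "+") "-" else "+"
    hitOpp <- tab$chrom == chrom & tab$strand == opp &
        tab$start <= pos & tab$end > pos
    if (any(hitOpp))
        return(data.frame(category = "opposite_strand",
                          biotype = "opposite_strand",
                          stringsAsFactors = FALSE))
    data.frame(category = "intergenic", biotype = "intergenic",
               stringsAsFactors = FALSE)
}

.pairKeysToTable <- function(keys) {
    parts <- strsplit(keys, "\t", fixed = TRUE)
    out <- data.frame(category = vapply(parts, `[`, character(1), 1),
                      biotype = vapply(parts, `[`, character(1), 2),
                      stringsAsFactors = FALSE)
    out[order(.categoryRank(out$category), out$biotype), , drop = FALSE]
}

#' Intersect a coverage track with the feature index
#'
#' Aggregates the track's nucleotide coverage into counts per
#' category-biotype pair at the chosen depth. The result is equivalent to
#' summing `depth x classifyPosition` over every covered nucleotide, but is
#' computed by splitting coverage intervals against the index intervals
#' (interval overlap joins, never per-position loops). Ambiguous
#' nucleotides — more than one pair at the reporting depth — are discarded
#' and tallied under the default policy or split equally among the pairs
#' under the split policy; the discarded percentage is reported on the
#' message stream. Chromosomes present in the track but absent from the
#' index are skipped with a warning and tallied.
#'
#' @param track a [CoverageTrack].
#' @param index a [FeatureIndex]; the variant matching the track's strand
#'   mode must be loaded.
#' @param depth reporting depth, 1..4.
#' @param ambiguityPolicy `"discard"` (default) or `"split"`.
#' @return A [FeatureCounts].
#' @export
intersectCounts <- function(track, index, depth = 3L,
                            ambiguityPolicy = c("discard", "split")) {
    stopifnot(is(track, "CoverageTrack"), is(index, "FeatureIndex"))
    ambiguityPolicy <- match.arg(ambiguityPolicy)
    if (!depth %in% 1:4) stop("depth must be in 1..4")
    depth <- as.integer(depth)
    stranded <- track@strandMode != "unstranded"
    tab <- if (stranded) index@stranded else index@unstranded
    if (!nrow(tab))
        stop("the ", if (stranded) "stranded" else "unstranded",
             " index variant is empty; was only the other variant loaded?")

    acc <- new.env(parent = emptyenv())
    acc$pairs <- numeric()
    acc$ambiguous <- 0
    unmatched <- 0
    cls <- .classifyAnnots(tab$annot, depth)

    iv <- track@intervals
    idxChroms <- unique(tab$chrom)
    for (ch in unique(iv$chrom)) {
        tsub <- iv[iv$chrom == ch, , drop = FALSE]
        if (!ch %in% idxChroms) {
            warning("chromosome ", ch, " is absent from the index; ",
                    "its coverage is skipped")
            unmatched <- unmatched +
                sum((tsub$end - tsub$start) * tsub$depth)
            next
        }
        isub <- tab[tab$chrom == ch, , drop = FALSE]
        if (!stranded) {
            .intersectStrand(acc, tsub, isub, NULL, cls, ambiguityPolicy)
        } else {
            for (s in c("+", "-")) {
                .intersectStrand(acc,
                                 tsub[tsub$strand == s, , drop = FALSE],
                                 isub[isub$strand == s, , drop = FALSE],
                                 isub[isub$strand != s, , drop = FALSE],
                                 cls, ambiguityPolicy)
            }
        }
    }

    total <- trackTotal(track)
    assigned <- total - acc$ambiguous - unmatched
    if (total > 0)
        message(sprintf("%s: ambiguous: %.2f%% of nucleotides discarded",
                        track@sampleLabel, 100 * acc$ambiguous / total))
    new("FeatureCounts",
        sampleLabel = track@sampleLabel, depth = depth,
        strandMode = track@strandMode, ambiguityPolicy = ambiguityPolicy,
        counts = .pairsToTable(acc$pairs, valueName = "count"),
        ambiguousDiscarded = acc$ambiguous,
        unmatchedChromDiscarded = unmatched,
        trackTotal = total)
}

# vectorized overlap join between two sorted disjoint interval sets
# (0-based half-open vectors); returns parallel vectors of query index,
# subject index and overlap width
.overlapPairs <- function(as, ae, bs, be) {
    if (!length(as) || !length(bs))
        return(list(q = integer(), s = integer(), w = integer()))
    j1 <- findInterval(as, be) + 1L           # first b with b.end > a.start
    j2 <- findInterval(ae - 1L, bs)           # last b with b.start < a.end
    n <- pmax(0L, j2 - j1 + 1L)
    keep <- n > 0L
    q <- rep(which(keep), n[keep])
    s <- sequence(n[keep], from = j1[keep])
    w <- pmin(ae[q], be[s]) - pmax(as[q], bs[s])
    list(q = q, s = s, w = w)
}

# one chrom, one assigned strand: overlap coverage with the index intervals,
# classify the remainder as opposite_strand (covered on the other strand) or
# intergenic. `oppIdx` is NULL in unstranded mode (no opposite_strand there).
.intersectStrand <- function(acc, tsub, isub, oppIdx, cls, policy) {
    if (!nrow(tsub)) return(invisible())
    as <- tsub$start; ae <- tsub$end; d <- tsub$depth
    remWidth <- ae - as
    if (nrow(isub)) {
        ov <- .overlapPairs(as, ae, isub$start, isub$end)
        if (length(ov$q)) {
            byAnnot <- rowsum(ov$w * d[ov$q], isub$annot[ov$s])
            .accumulate(acc, cls[rownames(byAnnot)],
                        as.numeric(byAnnot), policy)
            covByQ <- rowsum(ov$w, ov$q)
            hit <- as.integer(rownames(covByQ))
            remWidth[hit] <- remWidth[hit] - as.numeric(covByQ)
        }
    }
    # remainder: per track interval, the uncovered part
    if (!any(remWidth > 0)) return(invisible())
    if (is.null(oppIdx)) {
        .addPair(acc, "intergenic\tintergenic", sum(remWidth * d))
        return(invisible())
    }
    # stranded mode: cut the remainder into pieces (track minus index) and
    # split them against the opposite-strand annotation
    win <- c(min(as), max(ae))
    if (nrow(isub)) {
        gs <- c(win[1], isub$end)
        ge <- c(isub$start, win[2])
        ok <- gs < ge
        gs <- gs[ok]; ge <- ge[ok]
    } else {
        gs <- win[1]; ge <- win[2]
    }
    pv <- .overlapPairs(as, ae, gs, ge)
    if (!length(pv$q)) return(invisible())
    pStart <- pmax(as[pv$q], gs[pv$s])
    pEnd <- pStart + pv$w
    pieceNt <- pv$w * d[pv$q]
    oppCovered <- rep(0, length(pStart))
    if (nrow(oppIdx)) {
        oOv <- .overlapPairs(pStart, pEnd, oppIdx$start, oppIdx$end)
        if (length(oOv$q)) {
            owByPiece <- rowsum(oOv$w * d[pv$q[oOv$q]], oOv$q)
            oppCovered[as.integer(rownames(owByPiece))] <-
                as.numeric(owByPiece)
        }
    }
    .addPair(acc, "opposite_strand\topposite_strand", sum(oppCovered))
    .addPair(acc, "intergenic\tintergenic", sum(pieceNt - oppCovered))
    invisible()
}

#' Count several samples against one index
#'
#' Applies [intersectCounts] to each track, optionally across worker
#' processes (one sample per worker). Results are identical to a serial run
#' whatever the worker count; any sample failure aborts the batch naming
#' the failing sample.
#'
#' @param tracks list of [CoverageTrack] objects.
#' @param index a [FeatureIndex].
#' @param depth reporting depth, 1..4.
#' @param ambiguityPolicy `"discard"` or `"split"`.
#' @param workers number of worker processes (forked; 1 = serial).
#' @return List of [FeatureCounts], one per track, in input order.
#' @export
countSamples <- function(tracks, index, depth = 3L,
                         ambiguityPolicy = c("discard", "split"),
                         workers = 1L) {
    ambiguityPolicy <- match.arg(ambiguityPolicy)
    stopifnot(workers >= 1)
    run <- function(tr) tryCatch(
        intersectCounts(tr, index, depth = depth,
                        ambiguityPolicy = ambiguityPolicy),
        error = function(e) structure(
            list(label = tr@sampleLabel, msg = conditionMessage(e)),
            class = "readscapeSampleError"))
    results <- if (workers == 1L) lapply(tracks, run) else
        parallel::mclapply(tracks, run, mc.cores = workers)
    for (r in results)
        if (inherits(r, "readscapeSampleError"))
            stop("sample ", r$label, " failed: ", r$msg)
    results
}

#' Write feature counts (with genome sizes) to a TSV file
#'
#' One row per sample and per category-biotype pair present in the genome
#' size table: pairs with genomic presence but no reads are written with
#' count 0, pairs absent from the genome cannot occur in counts (a pair in
#' the counts but missing from the sizes indicates an index/depth mismatch
#' and is a hard error). Rows are ordered by sample, category hierarchy,
#' biotype, so the file is deterministic.
#'
#' @param results list of [FeatureCounts] (or a single one).
#' @param sizes genome size table from [genomeSizes], computed at the same
#'   depth and strand variant.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureCounts <- function(results, sizes, path) {
    if (is(results, "FeatureCounts")) results <- list(results)
    sizeKey <- paste(sizes$category, sizes$biotype, sep = "\t")
    rows <- lapply(results, function(fc) {
        ct <- fc@counts
        key <- paste(ct$category, ct$biotype, sep = "\t")
        missing <- setdiff(key, sizeKey)
        if (length(missing))
            stop("counts for sample ", fc@sampleLabel, " contain pair(s) ",
                 paste(gsub("\t", "/", missing), collapse = ", "),
                 " absent from the genome size table; ",
                 "index, depth or strand variant mismatch")
        cnt <- stats::setNames(ct$count, key)[sizeKey]
        cnt[is.na(cnt)] <- 0
        data.frame(sample = fc@sampleLabel, category = sizes$category,
                   biotype = sizes$biotype, nucleotide_count = unname(cnt),
                   genome_size = sizes$size, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a feature counts TSV written by [writeFeatureCounts]
#'
#' @param path the TSV path.
#' @return data.frame with columns sample, category, biotype,
#'   nucleotide_count, genome_size.
#' @export
readFeatureCounts <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE)
}
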