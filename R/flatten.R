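#' @importFrom IRanges IRanges disjoin reduce findOverlaps start end width
#' @importFrom S4Vectors queryHits subjectHits
NULL

# Per-gene annotation tokens --------------------------------------------------
#
# Every flat interval carries a set of per-gene annotation tokens encoding the
# full hierarchy chain at that position:
#
#     biotype|level2|level3labels|level4labels
#
# level2 is single-valued per gene (exon, intron or undescribed_gene); level3
# and level4 are comma-joined sorted label sets (different transcripts of the
# same gene may disagree, which is what positional ambiguity is). Level 1
# (gene) is implicit. Sets of tokens are ";"-joined and sorted, so identical
# annotations from different genes/transcripts deduplicate and serialization
# is deterministic.

.makeToken <- function(biotype, l2, l3 = character(), l4 = character()) {
    paste(biotype, l2,
          paste(sort(unique(l3)), collapse = ","),
          paste(sort(unique(l4)), collapse = ","), sep = "|")
}

.splitToken <- function(token) {
    s <- strsplit(token, "|", fixed = TRUE)[[1]]
    length(s) <- 4L
    s[is.na(s)] <- ""
    s
}

# category-biotype pairs visible at `depth` for one ";"-joined annot string;
# returns a unique character vector of "category\tbiotype" keys
.tokenPairsAtDepth <- function(annot, depth) {
    tokens <- strsplit(annot, ";", fixed = TRUE)[[1]]
    out <- character()
    for (tok in tokens) {
        s <- .splitToken(tok)
        bt <- s[1]; l2 <- s[2]
        cats <- if (depth == 1L) {
            "gene"
        } else if (depth == 2L || l2 != "exon") {
            l2
        } else {
            l3 <- strsplit(s[3], ",", fixed = TRUE)[[1]]
            l4 <- strsplit(s[4], ",", fixed = TRUE)[[1]]
            if (depth == 4L && length(l4)) l4 else l3
        }
        out <- c(out, paste(cats, bt, sep = "\t"))
    }
    unique(out)
}

# memoized classification of many annot strings; returns a list keyed by
# annot string, each element a character vector of "category\tbiotype" keys
.classifyAnnots <- function(annots, depth) {
    u <- unique(annots)
    stats::setNames(lapply(u, .tokenPairsAtDepth, depth = depth), u)
}

# IRanges helpers: internal coordinates are 0-based half-open, IRanges are
# 1-based inclusive
.toIR <- function(start, end) IRanges(start = start + 1L, end = end)
.irStart0 <- function(ir) start(ir) - 1L
.irEnd0 <- function(ir) end(ir)

#' Flatten all GTF records of one gene into non-overlapping intervals
#'
#' Converts the overlapping records of a single gene (gene, transcript, exon,
#' CDS, UTR, codon lines across all its transcripts) into a tiling of the
#' gene span by non-overlapping intervals, each carrying the gene's
#' annotation chain at that position: level 2 is exon wherever any exon of
#' any transcript covers the position and intron elsewhere (undescribed_gene
#' when the gene has no exon records at all); level 3, within exons, is the
#' set of CDS/UTR labels covering the position, or undescribed_exon when
#' none does; level 4 is the start/stop codon label where a codon record
#' covers the position. When transcripts disagree at a level both labels are
#' kept, which marks positional ambiguity at that level.
#'
#' @param records data.frame of [parseGtf] rows sharing one `gene_id` (and
#'   therefore one chromosome and strand).
#'
#' @return data.frame (chrom, start, end, strand, annot) of non-overlapping
#'   intervals tiling the gene span, coordinates 0-based half-open.
#'
#' @details Stop codons, which Ensembl excludes from the CDS, carry the
#'   level-3 label CDS so that depth-3 reports treat them as coding sequence
#'   rather than as a 3 nt undescribed artifact. Bare "UTR" records (the
#'   pre-release-75 GTF dialect) are assigned five_prime/three_prime by their
#'   position relative to the gene's CDS span on its strand; without any CDS
#'   they contribute nothing and the region falls back to undescribed_exon.
#'   A child record extending outside the gene record's span extends the
#'   effective span with a warning.
#'
#' @export
flattenGene <- function(records) {
    stopifnot(nrow(records) >= 1,
              length(unique(records$gene_id)) == 1,
              length(unique(records$chrom)) == 1)
    chrom <- records$chrom[1]
    strand <- records$strand[1]

    geneRec <- records[records$feature == "gene", , drop = FALSE]
    spanStart <- min(records$start)
    spanEnd <- max(records$end)
    if (nrow(geneRec) &&
        (spanStart < geneRec$start[1] || spanEnd > geneRec$end[1]))
        warning("gene ", records$gene_id[1],
                ": child features extend outside the gene record span; ",
                "effective span extended")
    biotype <- if (nrow(geneRec)) geneRec$gene_biotype[1] else
        records$gene_biotype[1]

    # all per-gene work is done on plain (start, end) 0-based half-open
    # integer pairs: the scale is a handful of records per gene
    featRanges <- function(feat) {
        r <- records[records$feature %in% feat, , drop = FALSE]
        cbind(r$start, r$end)
    }
    exonR <- featRanges("exon")
    cdsR <- featRanges("CDS")
    startR <- featRanges("start_codon")
    stopR <- featRanges("stop_codon")
    utr5R <- featRanges("five_prime_utr")
    utr3R <- featRanges("three_prime_utr")

    # bare "UTR" dialect: split by the CDS span, label each side by strand
    bareR <- featRanges("UTR")
    if (nrow(bareR) && nrow(cdsR)) {
        cdsLo <- min(cdsR[, 1])
        cdsHi <- max(cdsR[, 2])
        for (j in seq_len(nrow(bareR))) {
            s <- bareR[j, 1]; e <- bareR[j, 2]
            before <- if (s < cdsLo) c(s, min(e, cdsLo)) else NULL
            after <- if (e > cdsHi) c(max(s, cdsHi), e) else NULL
            if (strand == "-") {
                if (!is.null(after)) utr5R <- rbind(utr5R, after)
                if (!is.null(before)) utr3R <- rbind(utr3R, before)
            } else {
                if (!is.null(before)) utr5R <- rbind(utr5R, before)
                if (!is.null(after)) utr3R <- rbind(utr3R, after)
            }
        }
    }

    # stop codon is coding sequence at level 3 (Ensembl excludes it from CDS)
    cdsEffR <- rbind(cdsR, stopR)

    bp <- c(spanStart, spanEnd,
            exonR, cdsEffR, utr5R, utr3R, startR, stopR)
    bp <- sort(unique(pmin(pmax(as.integer(bp), spanStart), spanEnd)))
    pStart <- bp[-length(bp)]
    pEnd <- bp[-1]

    coversPiece <- function(m) {
        hit <- rep(FALSE, length(pStart))
        for (j in seq_len(nrow(m)))
            hit <- hit | (pStart >= m[j, 1] & pEnd <= m[j, 2])
        hit
    }
    hasExons <- nrow(exonR) > 0
    inExon <- coversPiece(exonR)
    inCds <- coversPiece(cdsEffR)
    inU5 <- coversPiece(utr5R)
    inU3 <- coversPiece(utr3R)
    inStart <- coversPiece(startR)
    inStop <- coversPiece(stopR)

    annot <- character(length(pStart))
    for (i in seq_along(pStart)) {
        if (!hasExons) {
            annot[i] <- .makeToken(biotype, "undescribed_gene")
        } else if (!inExon[i]) {
            annot[i] <- .makeToken(biotype, "intron")
        } else {
            l3 <- c("CDS", "five_prime_utr", "three_prime_utr")[
                c(inCds[i], inU5[i], inU3[i])]
            if (!length(l3)) l3 <- "undescribed_exon"
            l4 <- c("start_codon", "stop_codon")[c(inStart[i], inStop[i])]
            annot[i] <- .makeToken(biotype, "exon", l3, l4)
        }
    }

    out <- data.frame(chrom = chrom, start = pStart, end = pEnd,
                      strand = strand, annot = annot,
                      stringsAsFactors = FALSE)
    .mergeAdjacent(out)
}

# merge adjacent intervals with identical annotation (one chrom+strand table)
.mergeAdjacent <- function(df) {
    if (nrow(df) < 2) return(df)
    df <- df[order(df$chrom, df$strand, df$start), , drop = FALSE]
    newRun <- c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)] |
                      df$strand[-1] != df$strand[-nrow(df)] |
                      df$annot[-1] != df$annot[-nrow(df)] |
                      df$start[-1] != df$end[-nrow(df)])
    run <- cumsum(newRun)
    out <- df[newRun, , drop = FALSE]
    out$end <- as.integer(vapply(split(df$end, run), max, numeric(1)))
    rownames(out) <- NULL
    out
}

# merge flattened per-gene tables genome-wide: disjoin per chrom(+strand) and
# union the token sets; `byStrand = FALSE` collapses strands (unstranded index)
.mergeFlat <- function(df, byStrand = TRUE) {
    if (!nrow(df)) return(.emptyIndexTable())
    key <- if (byStrand) paste(df$chrom, df$strand) else df$chrom
    pieces <- lapply(split(seq_len(nrow(df)), key), function(idx) {
        sub <- df[idx, , drop = FALSE]
        ir <- .toIR(sub$start, sub$end)
        dj <- disjoin(ir)
        ov <- findOverlaps(dj, ir)
        toks <- split(sub$annot[subjectHits(ov)], queryHits(ov))
        annot <- vapply(toks, function(t)
            paste(sort(unique(unlist(strsplit(t, ";", fixed = TRUE)))),
                  collapse = ";"), character(1))
        covered <- as.integer(names(toks))
        dj <- dj[covered]
        o <- order(start(dj))
        .mergeAdjacent(data.frame(
            chrom = sub$chrom[1], start = .irStart0(dj)[o],
            end = .irEnd0(dj)[o],
            strand = if (byStrand) sub$strand[1] else ".",
            annot = annot[o], stringsAsFactors = FALSE))
    })
    out <- do.call(rbind, pieces)
    out <- out[order(out$chrom, out$strand, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Build the stranded and unstranded feature indexes from GTF records
#'
#' Groups parsed GTF records by gene, flattens each gene with [flattenGene]
#' and merges the per-gene tilings genome-wide: positions covered by several
#' genes on the same strand carry the union of their annotation chains
#' (identical chains deduplicate; differing chains mark ambiguity), and the
#' unstranded variant is the per-position union of both strands. Features on
#' strand "." are placed on both strands of the stranded index. The result
#' is deterministic: identical input yields an identical index.
#'
#' @param records data.frame from [parseGtf].
#' @param chromLengths optional named integer vector of chromosome lengths;
#'   usually left empty and supplied from the BAM header at categorization
#'   time.
#' @param sourceDigest optional md5 checksum of the source GTF.
#'
#' @return A [FeatureIndex].
#' @seealso [indexGtf] to go directly from a GTF file path.
#' @export
buildFeatureIndex <- function(records, chromLengths = integer(),
                              sourceDigest = NA_character_) {
    if (!nrow(records)) stop("no usable features in the annotation")
    flats <- lapply(split(records, records$gene_id), flattenGene)
    flat <- do.call(rbind, flats)
    rownames(flat) <- NULL

    # strandless features live on both strands of the stranded index
    dot <- flat$strand == "."
    strandedIn <- flat
    if (any(dot)) {
        dup <- flat[dot, , drop = FALSE]
        strandedIn$strand[dot] <- "+"
        dup$strand <- "-"
        strandedIn <- rbind(strandedIn, dup)
    }

    new("FeatureIndex",
        stranded = .mergeFlat(strandedIn, byStrand = TRUE),
        unstranded = .mergeFlat(flat, byStrand = FALSE),
        chromLengths = .asChromLengths(chromLengths),
        sourceDigest = sourceDigest)
}

.asChromLengths <- function(x) {
    if (!length(x)) return(integer())
    stopifnot(!is.null(names(x)))
    stats::setNames(as.integer(x), names(x))
}

#' Index a GTF file in one call
#'
#' Convenience wrapper: [parseGtf] then [buildFeatureIndex], recording the
#' file's md5 checksum for staleness detection on reuse.
#'
#' @inheritParams parseGtf
#' @inheritParams buildFeatureIndex
#' @return A [FeatureIndex].
#' @export
indexGtf <- function(path, chromLengths = integer()) {
    buildFeatureIndex(parseGtf(path), chromLengths = chromLengths,
                      sourceDigest = unname(tools::md5sum(path)))
}
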