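#' @importFrom GenomicAlignments readGAlignments grglist
#' @importFrom GenomicRanges GRanges coverage strand seqnames
#' @importFrom Rsamtools BamFile ScanBamParam scanBamFlag scanBamHeader
#'   indexBam
NULL

#' Compute per-strand nucleotide coverage from a BAM file
#'
#' Depth at a position is the number of primary alignments whose aligned
#' segments cover it, with split-read semantics: aligned bases and deletions
#' (CIGAR M/=/X/D) cover the reference, skipped regions (N, spliced introns)
#' do not, and insertions/clips contribute nothing. Unmapped, secondary and
#' supplementary alignments are excluded.
#'
#' Strand assignment follows the library strandness: in `forward` mode a
#' single-end read counts on its alignment strand, in `reverse` mode on the
#' opposite strand, and in `unstranded` mode a single merged track is
#' produced. For paired-end data the first mate defines the fragment strand
#' and the second mate is flipped before the mode is applied; paired reads
#' with inconsistent mate flags (neither or both mate bits set) are counted
#' normally in unstranded mode and skipped with a tally in the stranded
#' modes.
#'
#' @param bamPath path to a coordinate-sorted BAM file; a missing `.bai`
#'   index is built on the fly.
#' @param sampleLabel sample name; defaults to the BAM basename.
#' @param strandMode one of `"unstranded"`, `"forward"`, `"reverse"`.
#' @param minMapq minimum mapping quality; 0 (default) keeps every primary
#'   alignment.
#'
#' @return A [CoverageTrack]; chromosome lengths are taken from the BAM
#'   header.
#' @export
bamToCoverage <- function(bamPath, sampleLabel = NULL,
                          strandMode = c("unstranded", "forward", "reverse"),
                          minMapq = 0) {
    strandMode <- match.arg(strandMode)
    if (is.null(sampleLabel))
        sampleLabel <- sub("\\.bam$", "", basename(bamPath))
    if (!file.exists(bamPath)) stop("BAM file not found: ", bamPath)
    baiPath <- paste0(bamPath, ".bai")
    if (!file.exists(baiPath) &&
        !file.exists(sub("\\.bam$", ".bai", bamPath))) {
        tryCatch(indexBam(bamPath),
                 error = function(e) stop("BAM index missing and could not ",
                                          "be built for ", bamPath, ": ",
                                          conditionMessage(e)))
    }
    bf <- BamFile(bamPath)
    hdr <- scanBamHeader(bamPath)[[1]]$targets
    chromLengths <- .asChromLengths(hdr)

    flag <- scanBamFlag(isUnmappedQuery = FALSE,
                        isSecondaryAlignment = FALSE,
                        isSupplementaryAlignment = FALSE)
    param <- ScanBamParam(flag = flag, what = "flag",
                          mapqFilter = if (minMapq > 0) minMapq else NA)
    gal <- readGAlignments(bf, param = param)

    flags <- S4Vectors::mcols(gal)$flag
    paired <- bitwAnd(flags, 0x1L) > 0
    mate1 <- bitwAnd(flags, 0x40L) > 0
    mate2 <- bitwAnd(flags, 0x80L) > 0
    inconsistent <- paired & (mate1 == mate2)

    aln <- as.character(strand(gal))
    frag <- aln
    flip <- paired & mate2 & !inconsistent
    frag[flip] <- ifelse(aln[flip] == "+", "-", "+")

    if (strandMode == "unstranded") {
        assigned <- rep(".", length(gal))
    } else {
        if (any(inconsistent)) {
            message(sum(inconsistent), " paired alignment(s) with ",
                    "inconsistent mate flags skipped in stranded mode")
            gal <- gal[!inconsistent]
            frag <- frag[!inconsistent]
        }
        assigned <- if (strandMode == "forward") frag else
            ifelse(frag == "+", "-", "+")
    }

    iv <- .emptyCoverageTable()
    for (s in unique(assigned)) {
        blocks <- unlist(grglist(gal[assigned == s]), use.names = FALSE)
        cov <- coverage(blocks)
        iv <- rbind(iv, .rleListToIntervals(cov, s))
    }
    iv <- iv[order(iv$chrom, iv$strand, iv$start), , drop = FALSE]
    rownames(iv) <- NULL
    new("CoverageTrack", sampleLabel = sampleLabel, strandMode = strandMode,
        intervals = iv, chromLengths = chromLengths)
}

.rleListToIntervals <- function(covRleList, strandLabel) {
    out <- lapply(names(covRleList), function(ch) {
        r <- covRleList[[ch]]
        v <- S4Vectors::runValue(r)
        l <- S4Vectors::runLength(r)
        ends <- cumsum(as.numeric(l))
        starts <- ends - as.numeric(l)
        keep <- v > 0
        if (!any(keep)) return(NULL)
        data.frame(chrom = ch, start = as.integer(starts[keep]),
                   end = as.integer(ends[keep]), strand = strandLabel,
                   depth = as.numeric(v[keep]), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out)) .emptyCoverageTable() else out
}

#' Read bedgraph coverage into a CoverageTrack
#'
#' Bedgraph rows are taken verbatim (0-based half-open preserved); rows with
#' value zero are dropped. For stranded data supply the minus-strand file as
#' `minusPath`: the main file then holds the plus-strand coverage of the
#' alignments, and `strandMode = "reverse"` swaps the two files' strand
#' assignment (the library is reverse-stranded, so plus-strand alignments
#' came from minus-strand transcripts).
#'
#' @param path bedgraph file (chrom, start, end, value).
#' @param sampleLabel sample name; defaults to the file basename.
#' @param minusPath optional minus-strand bedgraph; when given, `path` is
#'   the plus-strand file.
#' @param strandMode `"unstranded"` (single-file, default), `"forward"` or
#'   `"reverse"` (two-file).
#' @param chromLengths optional named integer vector; bedgraph carries no
#'   chromosome lengths, so downstream normalization falls back to the
#'   annotation extent unless lengths are given here.
#' @return A [CoverageTrack].
#' @export
readBedgraph <- function(path, sampleLabel = NULL, minusPath = NULL,
                         strandMode = c("unstranded", "forward", "reverse"),
                         chromLengths = integer()) {
    strandMode <- match.arg(strandMode)
    if (is.null(sampleLabel))
        sampleLabel <- sub("(\\.plus|\\.minus)?\\.(bedgraph|bg)$", "",
                           basename(path))
    if (is.null(minusPath) && strandMode != "unstranded")
        stop("stranded bedgraph input needs both a plus and a minus file")
    if (!is.null(minusPath) && strandMode == "unstranded")
        stop("two bedgraph files given but strandMode is unstranded")

    plus <- .readBedgraphFile(path)
    if (is.null(minusPath)) {
        plus$strand <- rep(".", nrow(plus))
        iv <- plus
    } else {
        minus <- .readBedgraphFile(minusPath)
        if (strandMode == "forward") {
            plus$strand <- rep("+", nrow(plus))
            minus$strand <- rep("-", nrow(minus))
        } else {
            plus$strand <- rep("-", nrow(plus))
            minus$strand <- rep("+", nrow(minus))
        }
        iv <- rbind(plus, minus)
    }
    iv <- iv[order(iv$chrom, iv$strand, iv$start),
             c("chrom", "start", "end", "strand", "depth"), drop = FALSE]
    rownames(iv) <- NULL
    new("CoverageTrack", sampleLabel = sampleLabel, strandMode = strandMode,
        intervals = iv, chromLengths = .asChromLengths(chromLengths))
}

.readBedgraphFile <- function(path) {
    if (!file.exists(path)) stop("bedgraph file not found: ", path)
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") &
                   nzchar(trimws(lines))]
    if (!length(lines))
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), depth = numeric(),
                          stringsAsFactors = FALSE))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 4L)
    if (length(bad))
        stop("malformed bedgraph line ", bad[1], " in ", path)
    m <- matrix(unlist(lapply(fields, `[`, 1:4)), ncol = 4, byrow = TRUE)
    df <- data.frame(chrom = m[, 1],
                     start = as.integer(m[, 2]), end = as.integer(m[, 3]),
                     depth = as.numeric(m[, 4]), stringsAsFactors = FALSE)
    if (anyNA(df$start) || anyNA(df$end) || anyNA(df$depth))
        stop("non-numeric coordinates or value in bedgraph ", path)
    if (any(df$depth < 0))
        stop("negative coverage value in bedgraph ", path)
    df <- df[df$depth > 0, , drop = FALSE]
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    for (ch in unique(df$chrom)) {
        sub <- df[df$chrom == ch, , drop = FALSE]
        if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
            stop("overlapping intervals in bedgraph ", path,
                 " on chromosome ", ch)
    }
    rownames(df) <- NULL
    df
}

#' Write a CoverageTrack as bedgraph file(s)
#'
#' Unstranded tracks produce `<basename>.bedgraph`; stranded tracks produce
#' the `<basename>.plus.bedgraph` / `<basename>.minus.bedgraph` pair (named
#' by assigned strand).
#'
#' @param track a [CoverageTrack].
#' @param basename output path prefix.
#' @return Character vector of the file path(s), invisibly.
#' @export
writeBedgraph <- function(track, basename) {
    stopifnot(is(track, "CoverageTrack"))
    iv <- track@intervals
    fmt <- function(df) sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end,
                                format(df$depth, trim = TRUE,
                                       scientific = FALSE))
    if (track@strandMode == "unstranded") {
        path <- paste0(basename, ".bedgraph")
        writeLines(fmt(iv), path)
        return(invisible(path))
    }
    paths <- c(paste0(basename, ".plus.bedgraph"),
               paste0(basename, ".minus.bedgraph"))
    writeLines(fmt(iv[iv$strand == "+", , drop = FALSE]), paths[1])
    writeLines(fmt(iv[iv$strand == "-", , drop = FALSE]), paths[2])
    invisible(paths)
}
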