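#' @import methods
NULL

# Internal interval table schema (all coordinates 0-based, half-open):
#   index tables:    chrom, start, end, strand, annot
#   coverage tables: chrom, start, end, strand, depth
# `annot` is a ";"-joined, sorted set of per-gene annotation tokens of the
# form "biotype|level2|level3labels|level4labels" (see flatten.R).

.emptyIndexTable <- function() {
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), annot = character(),
               stringsAsFactors = FALSE)
}

.emptyCoverageTable <- function() {
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), depth = numeric(),
               stringsAsFactors = FALSE)
}

.checkIntervalTable <- function(df, cols) {
    if (!is.data.frame(df)) return("interval table must be a data.frame")
    missing <- setdiff(cols, names(df))
    if (length(missing))
        return(paste("interval table lacks columns:",
                     paste(missing, collapse = ", ")))
    if (nrow(df) && any(df$start >= df$end))
        return("intervals must satisfy start < end")
    # disjointness per chrom+strand
    if (nrow(df)) {
        key <- paste(df$chrom, df$strand)
        for (k in unique(key)) {
            sub <- df[key == k, , drop = FALSE]
            sub <- sub[order(sub$start), , drop = FALSE]
            if (nrow(sub) > 1 &&
                any(sub$start[-1] < sub$end[-nrow(sub)]))
                return(paste("overlapping intervals on", k))
        }
    }
    NULL
}

#' FeatureIndex: flattened category-biotype annotation of a genome
#'
#' Holds the two non-overlapping interval indexes derived from a GTF file: a
#' stranded index (annotations kept per strand) and an unstranded index (the
#' per-position union of both strands). Every interval carries the full set
#' of per-gene annotation chains covering it, so the category-biotype labels
#' at any hierarchy depth can be recovered without re-reading the GTF.
#'
#' @slot stranded data.frame of non-overlapping intervals (chrom, start, end,
#'   strand, annot), strand one of "+"/"-".
#' @slot unstranded data.frame of the same shape with strand ".".
#' @slot chromLengths named integer vector of chromosome lengths; may be
#'   empty (lengths are usually learned from the BAM header at
#'   categorization time, the GTF does not carry them).
#' @slot sourceDigest md5 checksum of the source GTF, used to detect stale
#'   index files.
#'
#' @export
setClass("FeatureIndex",
    representation(stranded = "data.frame",
                   unstranded = "data.frame",
                   chromLengths = "integer",
                   sourceDigest = "character"),
    prototype(stranded = .emptyIndexTable(),
              unstranded = .emptyIndexTable(),
              chromLengths = integer(),
              sourceDigest = NA_character_))

setValidity("FeatureIndex", function(object) {
    msg <- .checkIntervalTable(object@stranded,
                               c("chrom", "start", "end", "strand", "annot"))
    if (!is.null(msg)) return(paste("stranded:", msg))
    msg <- .checkIntervalTable(object@unstranded,
                               c("chrom", "start", "end", "strand", "annot"))
    if (!is.null(msg)) return(paste("unstranded:", msg))
    if (nrow(object@stranded) && nrow(object@unstranded) &&
        !setequal(unique(object@stranded$chrom),
                  unique(object@unstranded$chrom)))
        return("stranded and unstranded variants cover different chromosomes")
    if (nrow(object@stranded) &&
        !all(object@stranded$strand %in% c("+", "-")))
        return("stranded index strands must be '+' or '-'")
    TRUE
})

#' CoverageTrack: per-strand nucleotide read coverage of one sample
#'
#' Bedgraph-style non-overlapping intervals with read depth, one list per
#' strand in the stranded modes or a single merged list in unstranded mode.
#' Coordinates are 0-based half-open throughout.
#'
#' @slot sampleLabel sample name used in outputs and plots.
#' @slot strandMode one of "unstranded", "forward", "reverse" (the library
#'   strandness: how a read's alignment strand maps to the transcript strand).
#' @slot intervals data.frame (chrom, start, end, strand, depth); strand is
#'   "." in unstranded mode.
#' @slot chromLengths named integer vector, from the BAM header (or inferred
#'   for bedgraph input).
#'
#' @export
setClass("CoverageTrack",
    representation(sampleLabel = "character",
                   strandMode = "character",
                   intervals = "data.frame",
                   chromLengths = "integer"),
    prototype(sampleLabel = NA_character_,
              strandMode = "unstranded",
              intervals = .emptyCoverageTable(),
              chromLengths = integer()))

setValidity("CoverageTrack", function(object) {
    if (!object@strandMode %in% c("unstranded", "forward", "reverse"))
        return("strandMode must be unstranded, forward or reverse")
    msg <- .checkIntervalTable(object@intervals,
                               c("chrom", "start", "end", "strand", "depth"))
    if (!is.null(msg)) return(msg)
    if (nrow(object@intervals) && any(object@intervals$depth < 0))
        return("coverage depth must be non-negative")
    TRUE
})

#' FeatureCounts: nucleotide counts per category-biotype pair for one sample
#'
#' The result of intersecting a [CoverageTrack] with a [FeatureIndex] at a
#' chosen hierarchy depth: every covered nucleotide contributes its depth to
#' the category-biotype pair annotating its position, ambiguous positions
#' (more than one pair at the reporting depth) are discarded and tallied, or
#' split equally under the split policy.
#'
#' @slot sampleLabel sample name.
#' @slot depth reporting depth, 1..4.
#' @slot strandMode strandness the track was computed with.
#' @slot ambiguityPolicy "discard" or "split".
#' @slot counts data.frame (category, biotype, count).
#' @slot ambiguousDiscarded nucleotides discarded as ambiguous.
#' @slot unmatchedChromDiscarded nucleotides on chromosomes absent from the
#'   index.
#' @slot trackTotal total aligned nucleotides of the input track, for
#'   conservation checks.
#'
#' @export
setClass("FeatureCounts",
    representation(sampleLabel = "character",
                   depth = "integer",
                   strandMode = "character",
                   ambiguityPolicy = "character",
                   counts = "data.frame",
                   ambiguousDiscarded = "numeric",
                   unmatchedChromDiscarded = "numeric",
                   trackTotal = "numeric"))

setValidity("FeatureCounts", function(object) {
    if (!object@depth %in% 1:4) return("depth must be in 1..4")
    if (!all(c("category", "biotype", "count") %in% names(object@counts)))
        return("counts must have columns category, biotype, count")
    if (nrow(object@counts) && any(object@counts$count < 0))
        return("counts must be non-negative")
    if (nrow(object@counts) &&
        !all(object@counts$category %in% names(categoryLevels())))
        return("unknown category name in counts")
    TRUE
})

setMethod("show", "FeatureIndex", function(object) {
    cat("FeatureIndex with", nrow(object@stranded), "stranded and",
        nrow(object@unstranded), "unstranded intervals on",
        length(unique(object@unstranded$chrom)), "chromosome(s)\n")
    if (length(object@chromLengths))
        cat("  chromosome lengths:",
            paste0(names(object@chromLengths), "=", object@chromLengths,
                   collapse = ", "), "\n")
})

setMethod("show", "CoverageTrack", function(object) {
    cat("CoverageTrack", sQuote(object@sampleLabel),
        paste0("(", object@strandMode, "):"),
        nrow(object@intervals), "intervals,",
        format(trackTotal(object), big.mark = ","),
        "aligned nucleotides\n")
})

setMethod("show", "FeatureCounts", function(object) {
    cat("FeatureCounts", sQuote(object@sampleLabel),
        "at depth", object@depth,
        paste0("(", object@strandMode, ", ", object@ambiguityPolicy, "):"),
        nrow(object@counts), "category-biotype pairs\n")
    tot <- object@trackTotal
    if (tot > 0)
        cat(sprintf("  ambiguous: %.2f%% of nucleotides discarded\n",
                    100 * object@ambiguousDiscarded / tot))
})
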