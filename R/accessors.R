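#' Accessors for readscape classes
#'
#' @param x a [FeatureIndex], [CoverageTrack] or [FeatureCounts] object.
#' @name accessors
NULL

#' @describeIn accessors the stranded interval table of a FeatureIndex.
#' @export
strandedIndex <- function(x) {
    stopifnot(is(x, "FeatureIndex"))
    x@stranded
}

#' @describeIn accessors the unstranded interval table of a FeatureIndex.
#' @export
unstrandedIndex <- function(x) {
    stopifnot(is(x, "FeatureIndex"))
    x@unstranded
}

#' @describeIn accessors named chromosome lengths (possibly empty).
#' @export
chromLengths <- function(x) {
    if (is(x, "FeatureIndex") || is(x, "CoverageTrack"))
        return(x@chromLengths)
    stop("no chromLengths for this object")
}

#' @describeIn accessors sample label.
#' @export
sampleLabel <- function(x) {
    stopifnot(is(x, "CoverageTrack") || is(x, "FeatureCounts"))
    x@sampleLabel
}

#' @describeIn accessors strandness mode.
#' @export
strandMode <- function(x) {
    stopifnot(is(x, "CoverageTrack") || is(x, "FeatureCounts"))
    x@strandMode
}

#' @describeIn accessors coverage interval table of a CoverageTrack.
#' @export
coverageIntervals <- function(x) {
    stopifnot(is(x, "CoverageTrack"))
    x@intervals
}

#' @describeIn accessors total aligned nucleotides of a CoverageTrack
#'   (sum of interval length times depth).
#' @export
trackTotal <- function(x) {
    stopifnot(is(x, "CoverageTrack"))
    iv <- x@intervals
    if (!nrow(iv)) return(0)
    sum((iv$end - iv$start) * iv$depth)
}

#' @describeIn accessors counts table (category, biotype, count) of a
#'   FeatureCounts.
#' @export
countsTable <- function(x) {
    stopifnot(is(x, "FeatureCounts"))
    x@counts
}

#' @describeIn accessors nucleotides discarded as ambiguous.
#' @export
ambiguousDiscarded <- function(x) {
    stopifnot(is(x, "FeatureCounts"))
    x@ambiguousDiscarded
}

#' @describeIn accessors nucleotides discarded on chromosomes absent from
#'   the index.
#' @export
unmatchedChromDiscarded <- function(x) {
    stopifnot(is(x, "FeatureCounts"))
    x@unmatchedChromDiscarded
}
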