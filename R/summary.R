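#' Summarize feature counts along one axis
#'
#' Marginalizes a sample's category-biotype counts over the other axis and
#' computes, per feature, the raw fraction of the sample's assigned
#' nucleotides, the fraction of the genome annotated with that feature, and
#' the enrichment score — raw fraction divided by genome fraction, so 1
#' means the sample follows the genomic distribution. The raw-fraction
#' denominator is the assigned signal only: nucleotides discarded as
#' ambiguous (reported separately) are excluded so the displayed fractions
#' sum to 1.
#'
#' @param counts a [FeatureCounts].
#' @param sizes genome size table from [genomeSizes] at the same depth and
#'   strand variant.
#' @param axis `"categories"` or `"biotypes"`.
#' @return data.frame with columns `sample`, `feature`, `raw_count`,
#'   `raw_fraction`, `genome_fraction`, `enrichment`; one row per feature of
#'   the genome-size marginal (features without reads appear with 0).
#' @export
summarizeCounts <- function(counts, sizes,
                            axis = c("categories", "biotypes")) {
    stopifnot(is(counts, "FeatureCounts"))
    axis <- match.arg(axis)
    ct <- counts@counts
    if (!nrow(ct) || sum(ct$count) == 0)
        stop("empty sample: ", counts@sampleLabel,
             " has no assigned nucleotides")
    col <- if (axis == "categories") "category" else "biotype"

    unknown <- setdiff(unique(ct[[col]]), unique(sizes[[col]]))
    if (length(unknown))
        stop("feature(s) ", paste(unknown, collapse = ", "),
             " counted but absent from the genome size table; ",
             "index, depth or strand variant mismatch")

    sizeMarg <- rowsum(sizes$size, sizes[[col]])
    features <- rownames(sizeMarg)
    cntMarg <- rowsum(ct$count, ct[[col]])
    cnt <- stats::setNames(rep(0, length(features)), features)
    cnt[rownames(cntMarg)] <- cntMarg[, 1]

    if (axis == "categories") {
        features <- features[order(.categoryRank(features))]
    } else {
        features <- features[order(-cnt[features], features)]
    }
    rawFrac <- cnt[features] / sum(cnt)
    genFrac <- sizeMarg[features, 1] / sum(sizeMarg)
    data.frame(sample = counts@sampleLabel, feature = features,
               raw_count = unname(cnt[features]),
               raw_fraction = unname(rawFrac),
               genome_fraction = unname(genFrac),
               enrichment = unname(rawFrac / genFrac),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Align one feature's raw fractions across samples
#'
#' Supports replicate screens: extracts, for one feature, the raw fraction
#' of each sample's summary table, aligned by sample. No statistics are
#' computed.
#'
#' @param tables list of summary tables from [summarizeCounts], sharing the
#'   same axis and depth.
#' @param feature the feature (category or biotype) to extract.
#' @return Named numeric vector of raw fractions, one per sample.
#' @export
compareSamples <- function(tables, feature) {
    if (is.data.frame(tables)) tables <- list(tables)
    vals <- vapply(tables, function(tb) {
        hit <- tb$feature == feature
        if (any(hit)) tb$raw_fraction[hit][1] else NA_real_
    }, numeric(1))
    names(vals) <- vapply(tables, function(tb) tb$sample[1], character(1))
    if (all(is.na(vals)))
        stop("feature ", feature, " is absent from every summary table")
    vals[is.na(vals)] <- 0
    vals
}

#' Write a summary table to TSV
#'
#' @param table summary table from [summarizeCounts] (or several rbound).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeSummary <- function(table, path) {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
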