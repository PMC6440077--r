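#' Genomic nucleotides per category-biotype pair
#'
#' Computes the normalization denominator of the enrichment score: for each
#' category-biotype pair at the chosen reporting depth, the number of
#' genomic nucleotides annotated with that pair. Positions that are
#' ambiguous at the reporting depth (more than one pair) are discarded and
#' tallied under the default policy, or split equally under the split
#' policy, mirroring how sample nucleotides are counted. Intergenic extent
#' needs chromosome lengths, which the GTF does not carry: they are taken
#' from `chromLengths` (usually the BAM header, passed through at
#' categorization time), falling back to lengths stored in the index, then
#' to the last annotated position per chromosome.
#'
#' In the stranded variant every chromosome contributes twice its length
#' (one count per strand): positions unannotated on one strand but facing
#' annotation on the other are `opposite_strand`, positions unannotated on
#' both strands count as `intergenic` once per strand.
#'
#' @param index a [FeatureIndex].
#' @param depth reporting depth, 1..4.
#' @param strandVariant `"unstranded"` or `"stranded"`.
#' @param chromLengths named integer vector of chromosome lengths; see
#'   Details above for the fallbacks.
#' @param ambiguityPolicy `"discard"` (default) or `"split"`.
#'
#' @return data.frame with columns `category`, `biotype`, `size`, sorted by
#'   category hierarchy then biotype, with attributes `ambiguous` (discarded
#'   nucleotides) and `total` (total assigned + ambiguous, which equals the
#'   summed chromosome lengths, twice for the stranded variant).
#' @export
genomeSizes <- function(index, depth, strandVariant = c("unstranded",
                                                        "stranded"),
                        chromLengths = NULL,
                        ambiguityPolicy = c("discard", "split")) {
    stopifnot(is(index, "FeatureIndex"))
    strandVariant <- match.arg(strandVariant)
    ambiguityPolicy <- match.arg(ambiguityPolicy)
    if (!depth %in% 1:4) stop("depth must be in 1..4")
    tab <- if (strandVariant == "stranded") index@stranded else
        index@unstranded
    if (!nrow(tab)) stop("index variant '", strandVariant, "' is empty")

    chroms <- sort(unique(tab$chrom))
    lens <- .resolveLengths(chroms, chromLengths, index@chromLengths, tab)

    acc <- new.env(parent = emptyenv())
    acc$pairs <- numeric()
    acc$ambiguous <- 0
    cls <- .classifyAnnots(tab$annot, depth)
    .accumulate(acc, cls[tab$annot], tab$end - tab$start, ambiguityPolicy)

    for (ch in chroms) {
        sub <- tab[tab$chrom == ch, , drop = FALSE]
        len <- lens[[ch]]
        if (strandVariant == "unstranded") {
            covered <- sum(sub$end - sub$start)
            .addPair(acc, "intergenic\tintergenic", len - covered)
        } else {
            uPlus <- reduce(.toIR(sub$start[sub$strand == "+"],
                                  sub$end[sub$strand == "+"]))
            uMinus <- reduce(.toIR(sub$start[sub$strand == "-"],
                                   sub$end[sub$strand == "-"]))
            both <- sum(width(IRanges::union(uPlus, uMinus)))
            .addPair(acc, "opposite_strand\topposite_strand",
                     sum(width(IRanges::setdiff(uMinus, uPlus))) +
                     sum(width(IRanges::setdiff(uPlus, uMinus))))
            .addPair(acc, "intergenic\tintergenic", 2 * (len - both))
        }
    }

    out <- .pairsToTable(acc$pairs, valueName = "size")
    attr(out, "ambiguous") <- acc$ambiguous
    attr(out, "total") <- sum(out$size) + acc$ambiguous
    attr(out, "depth") <- as.integer(depth)
    attr(out, "strandVariant") <- strandVariant
    out
}

.resolveLengths <- function(chroms, supplied, stored, tab) {
    lens <- stats::setNames(vapply(chroms, function(ch)
        max(tab$end[tab$chrom == ch]), numeric(1)), chroms)
    for (src in list(stored, supplied)) {
        if (length(src)) {
            hit <- intersect(chroms, names(src))
            lens[hit] <- pmax(lens[hit], as.numeric(src[hit]))
        }
    }
    lens
}

# accumulate widths into the pair tally given per-interval classifications
.accumulate <- function(acc, classifications, widths, policy) {
    for (i in seq_along(widths)) {
        pairs <- classifications[[i]]
        w <- widths[i]
        if (length(pairs) == 1L) {
            .addPair(acc, pairs, w)
        } else if (policy == "discard") {
            acc$ambiguous <- acc$ambiguous + w
        } else {
            for (p in pairs) .addPair(acc, p, w / length(pairs))
        }
    }
}

.addPair <- function(acc, key, w) {
    if (w == 0) return(invisible())
    cur <- acc$pairs[key]
    acc$pairs[key] <- if (is.na(cur)) w else cur + w
    invisible()
}

.pairsToTable <- function(pairs, valueName = "count") {
    if (!length(pairs)) {
        out <- data.frame(category = character(), biotype = character())
        out[[valueName]] <- numeric()
        return(out)
    }
    parts <- strsplit(names(pairs), "\t", fixed = TRUE)
    out <- data.frame(category = vapply(parts, `[`, character(1), 1),
                      biotype = vapply(parts, `[`, character(1), 2),
                      stringsAsFactors = FALSE)
    out[[valueName]] <- unname(pairs)
    out <- out[order(.categoryRank(out$category), out$biotype), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}
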