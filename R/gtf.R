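#' Parse a GTF annotation file
#'
#' Reads an Ensembl-style GTF file and returns its usable feature records as
#' a data.frame, with coordinates converted to the package-internal 0-based
#' half-open convention. Only features relevant to the category hierarchy
#' are retained (gene, transcript, exon, CDS, five_prime_utr,
#' three_prime_utr, the bare pre-release-75 "UTR", start_codon, stop_codon);
#' other feature types (Selenocysteine, ...) are skipped silently. Records
#' with no `gene_biotype` attribute get the biotype `"undescribed"` so that
#' incompletely annotated genes remain countable.
#'
#' @param path path to a GTF file; gzip-compressed input is read
#'   transparently.
#'
#' @return data.frame with columns `chrom`, `source`, `feature`, `start`
#'   (0-based), `end` (exclusive), `strand`, `gene_id`, `gene_biotype`,
#'   `transcript_id` (NA when absent), `line` (source line number), one row
#'   per retained feature line, in file order.
#'
#' @details Malformed lines (wrong column count, non-integer coordinates,
#'   end before start, an illegal strand symbol) and gene/transcript/exon
#'   records lacking `gene_id` are hard errors naming the offending line
#'   number: a damaged annotation must not silently skew the distribution.
#'
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste0("chr1\thavana\texon\t11\t40\t.\t+\t.\t",
#'                   "gene_id \"G1\"; gene_biotype \"protein_coding\";"), gtf)
#' parseGtf(gtf)
#' @export
parseGtf <- function(path) {
    if (!file.exists(path)) stop("GTF file not found: ", path)
    con <- gzfile(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
    lineno <- seq_along(lines)
    keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
    lines <- lines[keep]
    lineno <- lineno[keep]
    if (!length(lines)) return(.emptyGtfTable())

    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 9))
        stop("malformed GTF line ", lineno[which(nf < 9)[1]],
             ": expected 9 tab-delimited columns, got ", nf[which(nf < 9)[1]])
    m <- matrix(unlist(lapply(fields, `[`, 1:9)), ncol = 9, byrow = TRUE)

    feature <- m[, 3]
    sel <- feature %in% .GTF_FEATURES
    m <- m[sel, , drop = FALSE]
    lineno <- lineno[sel]
    if (!nrow(m)) return(.emptyGtfTable())

    start1 <- suppressWarnings(as.integer(m[, 4]))
    end1 <- suppressWarnings(as.integer(m[, 5]))
    bad <- which(is.na(start1) | is.na(end1))
    if (length(bad))
        stop("malformed GTF line ", lineno[bad[1]],
             ": non-integer coordinates")
    bad <- which(end1 < start1 | start1 < 1)
    if (length(bad))
        stop("malformed GTF line ", lineno[bad[1]],
             ": end < start or start < 1")
    strand <- m[, 7]
    bad <- which(!strand %in% c("+", "-", "."))
    if (length(bad))
        stop("malformed GTF line ", lineno[bad[1]],
             ": strand must be '+', '-' or '.'")

    attrs <- m[, 9]
    gene_id <- .gtfAttribute(attrs, "gene_id")
    biotype <- .gtfAttribute(attrs, "gene_biotype")
    transcript_id <- .gtfAttribute(attrs, "transcript_id")
    feature <- m[, 3]

    bad <- which(is.na(gene_id) &
                 feature %in% c("gene", "transcript", "exon"))
    if (length(bad))
        stop("GTF line ", lineno[bad[1]], ": ", feature[bad[1]],
             " record lacks gene_id")
    biotype[is.na(biotype)] <- "undescribed"

    data.frame(chrom = m[, 1], source = m[, 2], feature = feature,
               start = start1 - 1L, end = end1, strand = strand,
               gene_id = gene_id, gene_biotype = biotype,
               transcript_id = transcript_id, line = lineno,
               stringsAsFactors = FALSE)
}

.emptyGtfTable <- function() {
    data.frame(chrom = character(), source = character(),
               feature = character(), start = integer(), end = integer(),
               strand = character(), gene_id = character(),
               gene_biotype = character(), transcript_id = character(),
               line = integer(), stringsAsFactors = FALSE)
}

# extract `key "value";` (or unquoted `key value;`) from GTF attribute strings
.gtfAttribute <- function(attrs, key) {
    pat <- paste0('(?:^|;)\\s*', key, '\\s+"?([^";]*)"?')
    m <- regexpr(pat, attrs, perl = TRUE)
    out <- rep(NA_character_, length(attrs))
    ok <- m > 0
    if (any(ok))
        out[ok] <- sub(pat, "\\1", regmatches(attrs, m), perl = TRUE)
    out
}
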