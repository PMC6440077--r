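.INDEX_FORMAT_VERSION <- 1L

.indexPaths <- function(basename) {
    c(stranded = paste0(basename, ".stranded.index.tsv"),
      unstranded = paste0(basename, ".unstranded.index.tsv"))
}

.writeOneIndex <- function(df, variant, digest, chromLengths, path) {
    header <- c(
        paste0("# readscape feature index v", .INDEX_FORMAT_VERSION),
        paste0("# variant: ", variant),
        paste0("# source_digest: ", digest))
    if (length(chromLengths))
        header <- c(header, paste0("# chrom_lengths: ",
            paste0(names(chromLengths), "=", chromLengths, collapse = ",")))
    rows <- sprintf("%s\t%d\t%d\t%s\t%s",
                    df$chrom, df$start, df$end, df$strand, df$annot)
    con <- file(path, "wb")  # binary mode: byte-identical across platforms
    on.exit(close(con))
    writeLines(c(header, rows), con, sep = "\n")
    path
}

#' Write a FeatureIndex to its two reusable index files
#'
#' Serializes the stranded and unstranded variants to
#' `<basename>.stranded.index.tsv` and `<basename>.unstranded.index.tsv`:
#' a small commented header (format version, source GTF checksum, known
#' chromosome lengths) followed by tab-delimited rows `chrom`, `start`
#' (0-based), `end` (exclusive), `strand`, `annot`, sorted by chromosome and
#' start. Output is byte-identical for identical input, so the files can be
#' checksummed and cached.
#'
#' @param index a [FeatureIndex].
#' @param basename path prefix for the two files.
#' @return Named character vector of the two file paths, invisibly.
#' @export
writeFeatureIndex <- function(index, basename) {
    stopifnot(is(index, "FeatureIndex"))
    paths <- .indexPaths(basename)
    dir.create(dirname(basename), recursive = TRUE, showWarnings = FALSE)
    .writeOneIndex(index@stranded, "stranded", index@sourceDigest,
                   index@chromLengths, paths[["stranded"]])
    .writeOneIndex(index@unstranded, "unstranded", index@sourceDigest,
                   index@chromLengths, paths[["unstranded"]])
    invisible(paths)
}

.readOneIndex <- function(path) {
    lines <- readLines(path)
    if (!length(lines) || !startsWith(lines[1], "# readscape feature index v"))
        stop("not a readscape index file: ", path)
    version <- suppressWarnings(
        as.integer(sub("^# readscape feature index v", "", lines[1])))
    if (is.na(version) || version != .INDEX_FORMAT_VERSION)
        stop("index file ", path, " has unsupported format version; ",
             "please re-run indexing on the GTF")
    hdr <- grepl("^#", lines)
    digest <- sub("^# source_digest: ", "",
                  grep("^# source_digest: ", lines, value = TRUE))
    if (!length(digest)) digest <- NA_character_
    clLine <- grep("^# chrom_lengths: ", lines, value = TRUE)
    chromLengths <- integer()
    if (length(clLine)) {
        kv <- strsplit(strsplit(sub("^# chrom_lengths: ", "", clLine[1]),
                                ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
        chromLengths <- stats::setNames(
            as.integer(vapply(kv, `[`, character(1), 2)),
            vapply(kv, `[`, character(1), 1))
    }
    body <- lines[!hdr]
    if (!length(body))
        return(list(table = .emptyIndexTable(), digest = digest,
                    chromLengths = chromLengths))
    fields <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 5L)
    if (length(bad))
        stop("corrupt index file ", path, " at line ",
             which(!hdr)[bad[1]], ": expected 5 columns")
    m <- matrix(unlist(fields), ncol = 5, byrow = TRUE)
    start <- suppressWarnings(as.integer(m[, 2]))
    end <- suppressWarnings(as.integer(m[, 3]))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad))
        stop("corrupt index file ", path, " at line ",
             which(!hdr)[bad[1]], ": non-integer coordinates")
    list(table = data.frame(chrom = m[, 1], start = start, end = end,
                            strand = m[, 4], annot = m[, 5],
                            stringsAsFactors = FALSE),
         digest = digest, chromLengths = chromLengths)
}

#' Read a FeatureIndex back from disk
#'
#' @param basename the path prefix used with [writeFeatureIndex] (or the
#'   path of one of the two files, from which the prefix is derived).
#' @param variant which variant(s) to load; `"both"` (default) requires both
#'   files, a single variant reads only its file (enough when the strandness
#'   of the analysis is already fixed).
#' @return A [FeatureIndex]; an unloaded variant is left empty.
#' @export
readFeatureIndex <- function(basename, variant = c("both", "stranded",
                                                   "unstranded")) {
    variant <- match.arg(variant)
    basename <- sub("\\.(un)?stranded\\.index\\.tsv$", "", basename)
    paths <- .indexPaths(basename)
    want <- if (variant == "both") c("stranded", "unstranded") else variant
    missing <- want[!file.exists(paths[want])]
    if (length(missing))
        stop("index file(s) not found: ",
             paste(paths[missing], collapse = ", "))
    parts <- lapply(paths[want], .readOneIndex)
    str <- if ("stranded" %in% want) parts[["stranded"]]$table else
        .emptyIndexTable()
    uns <- if ("unstranded" %in% want) parts[["unstranded"]]$table else
        .emptyIndexTable()
    new("FeatureIndex", stranded = str, unstranded = uns,
        chromLengths = parts[[1]]$chromLengths,
        sourceDigest = parts[[1]]$digest)
}

#' @keywords internal
indexFilesExist <- function(basename) {
    all(file.exists(.indexPaths(basename)))
}
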