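#' Toy genome fixtures and the brute-force counting oracle
#'
#' These functions generate deterministic miniature genomes — a GTF, aligned
#' reads (in memory, as BAM, or as bedgraph) — with machine-readable ground
#' truth, so the whole pipeline can be exercised and verified without any
#' external data. [oracleCounts] is an intentionally naive independent
#' implementation of the counting semantics (it labels every covered
#' nucleotide by scanning all GTF records, with no index and no interval
#' sweep) and serves as the oracle the fast path is tested against.
#'
#' @name fixtures
NULL

#' The canonical single-gene toy specification
#'
#' One protein-coding gene on chr1:11-40(+) of a 100 nt chromosome, fully
#' exonic, with CDS 16-30, 5'UTR 11-15, 3'UTR 31-40 and start codon 16-18
#' (1-based inclusive, as in a GTF). Its flattened form and genome sizes
#' are small enough to verify by hand.
#'
#' @return A toy specification list (`chromLengths`, `genes`).
#' @export
toyGeneSpec <- function() {
    list(chromLengths = c(chr1 = 100L),
         genes = list(list(
             id = "G1", chrom = "chr1", strand = "+",
             biotype = "protein_coding", start = 11L, end = 40L,
             emitGene = TRUE,
             transcripts = list(list(
                 id = "G1.t1",
                 exons = list(c(11L, 40L)),
                 cds = list(c(16L, 30L)),
                 utr5 = list(c(11L, 15L)),
                 utr3 = list(c(31L, 40L)),
                 startCodon = list(c(16L, 18L)),
                 stopCodon = list(),
                 bareUtr = list())))))
}

.gtfAttrString <- function(geneId, biotype, txId = NULL) {
    s <- paste0('gene_id "', geneId, '";')
    if (!is.null(txId)) s <- paste0(s, ' transcript_id "', txId, '";')
    if (!is.na(biotype))
        s <- paste0(s, ' gene_biotype "', biotype, '";')
    s
}

#' Write a toy specification as a GTF file
#'
#' Emits deterministic GTF text for the specification, including any
#' deliberate pathology it encodes (overlapping genes, genes without exon
#' records, the bare "UTR" feature dialect, children outside the gene
#' span, missing gene_biotype attributes encoded as `biotype = NA`).
#'
#' @param spec a toy specification, e.g. from [toyGeneSpec] or
#'   [randomToySpec].
#' @param path output GTF path.
#' @return Invisibly, a manifest list: `path`, `nRecords`, and
#'   `featureCounts` (named record count per feature type).
#' @export
makeToyAnnotation <- function(spec, path) {
    lines <- character()
    emit <- function(chrom, feature, start, end, strand, attrs) {
        lines[[length(lines) + 1L]] <<- paste(chrom, "toy", feature, start,
                                              end, ".", strand, ".", attrs,
                                              sep = "\t")
    }
    for (g in spec$genes) {
        if (isTRUE(g$emitGene))
            emit(g$chrom, "gene", g$start, g$end, g$strand,
                 .gtfAttrString(g$id, g$biotype))
        for (tx in g$transcripts) {
            txSpan <- range(unlist(tx$exons))
            emit(g$chrom, "transcript", txSpan[1], txSpan[2], g$strand,
                 .gtfAttrString(g$id, g$biotype, tx$id))
            feats <- list(exon = tx$exons, CDS = tx$cds,
                          five_prime_utr = tx$utr5,
                          three_prime_utr = tx$utr3,
                          start_codon = tx$startCodon,
                          stop_codon = tx$stopCodon, UTR = tx$bareUtr)
            for (feat in names(feats))
                for (rg in feats[[feat]])
                    emit(g$chrom, feat, rg[1], rg[2], g$strand,
                         .gtfAttrString(g$id, g$biotype, tx$id))
        }
    }
    writeLines(c("#!toy annotation", lines), path)
    feats <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`,
                    character(1), 3)
    invisible(list(path = path, nRecords = length(lines),
                   featureCounts = c(table(feats))))
}

#' Generate a randomized toy specification
#'
#' Draws a small genome (1-2 chromosomes) with up to `maxGenes` genes whose
#' spans are placed independently, so same-strand and opposite-strand
#' overlaps occur by construction. Gene structures cover the interesting
#' space: gene-only records (undescribed at the exon level), multi-exon
#' transcripts, transcript pairs that disagree (positional ambiguity), CDS
#' with UTRs and codons, the bare "UTR" dialect, missing biotype
#' attributes, and children extending outside the gene record.
#'
#' @param seed integer seed; the spec is a deterministic function of it.
#' @param maxGenes maximum number of genes (at least 1).
#' @return A toy specification list.
#' @export
randomToySpec <- function(seed, maxGenes = 8L) {
    stopifnot(maxGenes >= 1)
    rng <- .seededRng(seed)
    nChrom <- rng$int(1, 2)
    lens <- vapply(seq_len(nChrom), function(i) rng$int(600, 2500),
                   integer(1))
    chroms <- paste0("chr", seq_len(nChrom))
    names(lens) <- chroms
    nGenes <- rng$int(1, maxGenes)
    biotypes <- c("protein_coding", "protein_coding", "miRNA", "lincRNA",
                  "rRNA", "snoRNA")
    genes <- vector("list", nGenes)
    for (i in seq_len(nGenes)) {
        chrom <- chroms[rng$int(1, nChrom)]
        len <- lens[[chrom]]
        gStart <- rng$int(1, max(1L, len - 150L))
        gEnd <- min(len, gStart + rng$int(30, 300))
        strand <- c("+", "-", "+", "-", ".")[rng$int(1, 5)]
        biotype <- if (rng$unif() < 0.08) NA_character_ else
            biotypes[rng$int(1, length(biotypes))]
        gene <- list(id = sprintf("G%02d", i), chrom = chrom,
                     strand = strand, biotype = biotype,
                     start = gStart, end = gEnd, emitGene = TRUE,
                     transcripts = list())
        if (rng$unif() < 0.15) {            # gene-only record
            genes[[i]] <- gene
            next
        }
        nTx <- rng$int(1, 2)
        for (t in seq_len(nTx)) {
            gene$transcripts[[t]] <-
                .randomTranscript(rng, gene, sprintf("%s.t%d", gene$id, t))
        }
        if (rng$unif() < 0.08 && length(gene$transcripts)) {
            # pathology: exon extending past the gene record span
            tx <- gene$transcripts[[1]]
            last <- length(tx$exons)
            tx$exons[[last]][2] <- tx$exons[[last]][2] + rng$int(3, 15)
            gene$transcripts[[1]] <- tx
        }
        genes[[i]] <- gene
    }
    list(chromLengths = lens, genes = genes)
}

.randomTranscript <- function(rng, gene, txId) {
    span <- gene$end - gene$start + 1L
    nExon <- if (span < 60) 1L else rng$int(1, 3)
    # cut the span into alternating exon/intron pieces
    bounds <- sort(unique(c(0L, span,
        if (nExon > 1) vapply(seq_len(2 * (nExon - 1)), function(i)
            rng$int(1, span - 1L), integer(1)))))
    while (length(bounds) < 2 * nExon + 1)
        bounds <- sort(unique(c(bounds, rng$int(1, span - 1L))))
    bounds <- bounds[seq_len(2 * nExon + 1)]
    bounds[2 * nExon + 1] <- span
    exons <- lapply(seq_len(nExon), function(k)
        c(gene$start + bounds[2 * k - 1], gene$start + bounds[2 * k] - 1L))
    exons <- Filter(function(e) e[2] >= e[1], exons)
    if (!length(exons)) exons <- list(c(gene$start, gene$end))

    tx <- list(id = txId, exons = exons, cds = list(), utr5 = list(),
               utr3 = list(), startCodon = list(), stopCodon = list(),
               bareUtr = list())
    if (rng$unif() < 0.6) {
        # place a CDS inside the exon with the widest extent
        widths <- vapply(exons, function(e) e[2] - e[1] + 1L, integer(1))
        host <- exons[[which.max(widths)]]
        if (host[2] - host[1] >= 12) {
            cs <- host[1] + rng$int(3, max(3L, (host[2] - host[1]) %/% 3))
            ce <- min(host[2] - 1L, cs + rng$int(6, 60))
            if (ce - cs >= 5) {
                tx$cds <- list(c(cs, ce))
                if (rng$unif() < 0.7)
                    tx$startCodon <- list(c(cs, min(ce, cs + 2L)))
                if (rng$unif() < 0.7)
                    tx$stopCodon <- list(c(max(cs, ce - 2L), ce))
                bare <- rng$unif() < 0.15
                if (rng$unif() < 0.7 && cs > host[1]) {
                    u <- c(host[1], cs - 1L)
                    if (bare) tx$bareUtr <- c(tx$bareUtr, list(u))
                    else if (gene$strand == "-")
                        tx$utr3 <- c(tx$utr3, list(u))
                    else tx$utr5 <- c(tx$utr5, list(u))
                }
                if (rng$unif() < 0.7 && ce < host[2]) {
                    u <- c(ce + 1L, host[2])
                    if (bare) tx$bareUtr <- c(tx$bareUtr, list(u))
                    else if (gene$strand == "-")
                        tx$utr5 <- c(tx$utr5, list(u))
                    else tx$utr3 <- c(tx$utr3, list(u))
                }
            }
        }
    }
    tx
}

# small deterministic RNG wrapper: keeps fixture randomness isolated from
# the global .Random.seed
.seededRng <- function(seed) {
    env <- new.env(parent = emptyenv())
    env$state <- local({
        old <- if (exists(".Random.seed", globalenv()))
            get(".Random.seed", globalenv()) else NULL
        set.seed(seed)
        st <- get(".Random.seed", globalenv())
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
        st
    })
    withState <- function(f) {
        old <- if (exists(".Random.seed", globalenv()))
            get(".Random.seed", globalenv()) else NULL
        assign(".Random.seed", env$state, globalenv())
        on.exit({
            env$state <- get(".Random.seed", globalenv())
            if (!is.null(old)) assign(".Random.seed", old, globalenv())
        })
        f()
    }
    list(int = function(lo, hi) {
             if (lo >= hi) return(as.integer(lo))
             withState(function() as.integer(sample(seq.int(lo, hi), 1L)))
         },
         unif = function() withState(function() stats::runif(1L)),
         state = env)
}

#' Generate random reads over a toy genome
#'
#' Single-end reads with uniform start positions; a fraction are spliced
#' (two aligned blocks separated by an N gap). Deterministic for a fixed
#' seed.
#'
#' @param spec toy specification (for chromosome names and lengths).
#' @param nReads number of reads.
#' @param seed integer seed.
#' @param splicedFraction fraction of reads given an N gap.
#' @return data.frame with columns `chrom`, `strand`, `start` (0-based
#'   leftmost), `cigar`, and a list-column `blocks` of (start, width)
#'   matrices (0-based half-open aligned segments).
#' @export
randomReads <- function(spec, nReads, seed, splicedFraction = 0.15) {
    rng <- .seededRng(seed)
    lens <- spec$chromLengths
    out <- vector("list", nReads)
    for (i in seq_len(nReads)) {
        chrom <- names(lens)[rng$int(1, length(lens))]
        len <- lens[[chrom]]
        w <- rng$int(5, 20)
        spliced <- rng$unif() < splicedFraction && len > 200
        if (spliced) {
            w2 <- rng$int(5, 15)
            gap <- rng$int(10, 100)
            start <- rng$int(0, max(0L, len - (w + gap + w2) - 1L))
            blocks <- rbind(c(start, w), c(start + w + gap, w2))
            cigar <- sprintf("%dM%dN%dM", w, gap, w2)
        } else {
            start <- rng$int(0, max(0L, len - w - 1L))
            blocks <- rbind(c(start, w))
            cigar <- sprintf("%dM", w)
        }
        out[[i]] <- list(chrom = chrom,
                         strand = c("+", "-")[rng$int(1, 2)],
                         start = start, cigar = cigar, blocks = blocks)
    }
    data.frame(chrom = vapply(out, `[[`, character(1), "chrom"),
               strand = vapply(out, `[[`, character(1), "strand"),
               start = vapply(out, function(x) as.integer(x$start),
                              integer(1)),
               cigar = vapply(out, `[[`, character(1), "cigar"),
               blocks = I(lapply(out, `[[`, "blocks")),
               stringsAsFactors = FALSE)
}

#' Plan-driven read placement within a region
#'
#' Places unspliced reads of length `readLen` uniformly within a region so
#' that their aligned nucleotides total exactly `nt` (the last read is
#' shortened if needed). Used to plant known signal (e.g. an inflated
#' intergenic fraction, or reads piled on start codons).
#'
#' @param chrom chromosome name.
#' @param start,end region, 0-based half-open.
#' @param nt total aligned nucleotides to plant.
#' @param strand read strand.
#' @param readLen read length.
#' @param seed integer seed.
#' @return reads data.frame as in [randomReads].
#' @export
plannedReads <- function(chrom, start, end, nt, strand = "+", readLen = 10L,
                         seed = 1L) {
    stopifnot(end - start >= readLen, nt >= 1)
    rng <- .seededRng(seed)
    widths <- c(rep(readLen, nt %/% readLen),
                if (nt %% readLen) nt %% readLen)
    out <- lapply(widths, function(w) {
        s <- rng$int(start, end - w)
        list(chrom = chrom, strand = strand, start = s,
             cigar = sprintf("%dM", w), blocks = rbind(c(s, w)))
    })
    data.frame(chrom = vapply(out, `[[`, character(1), "chrom"),
               strand = vapply(out, `[[`, character(1), "strand"),
               start = vapply(out, function(x) as.integer(x$start),
                              integer(1)),
               cigar = vapply(out, `[[`, character(1), "cigar"),
               blocks = I(lapply(out, `[[`, "blocks")),
               stringsAsFactors = FALSE)
}

#' Build a CoverageTrack directly from simulated reads
#'
#' Computes per-strand coverage in memory with the same semantics as
#' [bamToCoverage] on the equivalent BAM (aligned blocks cover, gaps do
#' not; forward mode keeps the alignment strand, reverse flips it,
#' unstranded merges).
#'
#' @param reads reads data.frame from [randomReads] / [plannedReads] (rbind
#'   several to mix).
#' @param chromLengths named integer vector.
#' @param sampleLabel sample name.
#' @param strandMode strandness mode.
#' @return A [CoverageTrack].
#' @export
readsToTrack <- function(reads, chromLengths, sampleLabel = "toy",
                         strandMode = c("unstranded", "forward",
                                        "reverse")) {
    strandMode <- match.arg(strandMode)
    assigned <- switch(strandMode,
        unstranded = rep(".", nrow(reads)),
        forward = reads$strand,
        reverse = ifelse(reads$strand == "+", "-", "+"))
    iv <- .emptyCoverageTable()
    for (s in unique(assigned)) {
        sel <- which(assigned == s)
        for (ch in unique(reads$chrom[sel])) {
            rsel <- sel[reads$chrom[sel] == ch]
            blocks <- do.call(rbind, reads$blocks[rsel])
            cov <- IRanges::coverage(
                IRanges(start = blocks[, 1] + 1L, width = blocks[, 2]),
                width = chromLengths[[ch]])
            iv <- rbind(iv, .rleListToIntervals(
                stats::setNames(IRanges::RleList(cov), ch), s))
        }
    }
    iv <- iv[order(iv$chrom, iv$strand, iv$start), , drop = FALSE]
    rownames(iv) <- NULL
    new("CoverageTrack", sampleLabel = sampleLabel, strandMode = strandMode,
        intervals = iv, chromLengths = .asChromLengths(chromLengths))
}

#' Write simulated reads as a sorted, indexed BAM file
#'
#' Minimal records: `@SQ`-only header plus synthetic read names, constant
#' base A sequence and `*` quality. Deterministic for fixed input.
#'
#' @param reads reads data.frame from [randomReads] / [plannedReads].
#' @param chromLengths named integer vector.
#' @param bamPath destination BAM path (`.bai` is written alongside).
#' @return `bamPath`, invisibly.
#' @export
writeToyBam <- function(reads, chromLengths, bamPath) {
    ord <- order(reads$chrom, reads$start)
    reads <- reads[ord, , drop = FALSE]
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", names(chromLengths),
                     chromLengths))
    qlen <- vapply(reads$blocks, function(b) sum(b[, 2]), numeric(1))
    recs <- sprintf("r%04d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                    seq_len(nrow(reads)),
                    ifelse(reads$strand == "-", 16L, 0L),
                    reads$chrom, reads$start + 1L, reads$cigar,
                    strrep("A", qlen))
    sam <- tempfile(fileext = ".sam")
    on.exit(unlink(sam))
    writeLines(c(hdr, recs), sam)
    tmp <- tempfile()
    Rsamtools::asBam(sam, destination = tmp, overwrite = TRUE,
                     indexDestination = FALSE)
    file.copy(paste0(tmp, ".bam"), bamPath, overwrite = TRUE)
    unlink(paste0(tmp, ".bam"))
    Rsamtools::indexBam(bamPath)
    invisible(bamPath)
}

#' Brute-force per-nucleotide counting oracle
#'
#' Independent verifier of the counting semantics: labels every covered
#' nucleotide of the track by scanning all GTF records directly — no index,
#' no interval arithmetic — then applies the same depth reduction,
#' opposite-strand and ambiguity rules. Intentionally naive
#' (O(positions x records)) and guarded to toy scale.
#'
#' @param gtf path to a GTF file, or a parsed record data.frame from
#'   [parseGtf].
#' @param track a [CoverageTrack]; its `strandMode` selects the semantics.
#' @param depth reporting depth, 1..4.
#' @param ambiguityPolicy `"discard"` or `"split"`.
#' @return A [FeatureCounts] comparable with [intersectCounts] output.
#' @export
oracleCounts <- function(gtf, track, depth = 3L,
                         ambiguityPolicy = c("discard", "split")) {
    ambiguityPolicy <- match.arg(ambiguityPolicy)
    records <- if (is.character(gtf)) parseGtf(gtf) else gtf
    iv <- track@intervals
    widths <- iv$end - iv$start
    if (sum(widths) > 2e5)
        stop("oracle is restricted to toy scale (<= 200 kb covered)")
    stranded <- track@strandMode != "unstranded"

    pos <- if (nrow(iv)) sequence(widths, from = iv$start) else integer()
    w <- rep(iv$depth, widths)
    chrom <- rep(iv$chrom, widths)
    rstrand <- rep(iv$strand, widths)

    # a chromosome with no annotation at all is not in any index: its
    # coverage is skipped and tallied, same as in the fast path
    known <- chrom %in% unique(records$chrom)
    unmatched <- sum(w[!known])
    pos <- pos[known]; w <- w[known]
    chrom <- chrom[known]; rstrand <- rstrand[known]

    oppCovered <- rep(FALSE, length(pos))
    labPos <- integer()     # position indices, repeated per label
    labKey <- character()   # the "category\tbiotype" label at that index

    for (gid in unique(records$gene_id)) {
        g <- records[records$gene_id == gid, , drop = FALSE]
        gStrand <- g$strand[1]
        gChrom <- g$chrom[1]
        span <- c(min(g$start), max(g$end))
        inSpan <- chrom == gChrom & pos >= span[1] & pos < span[2]
        if (stranded) {
            sense <- inSpan & (gStrand == "." | rstrand == gStrand)
            oppCovered <- oppCovered |
                (inSpan & gStrand != "." & rstrand != gStrand)
        } else {
            sense <- inSpan
        }
        idx <- which(sense)
        if (!length(idx)) next
        lab <- .oracleGeneLabels(g, pos[idx], depth)
        labPos <- c(labPos, idx[lab$idx])
        labKey <- c(labKey, lab$key)
    }

    # label-set signature per position, then aggregate weights by signature
    sig <- rep("", length(pos))
    if (length(labPos)) {
        bySig <- vapply(split(labKey, labPos), function(k)
            if (length(k) == 1L) k else
                paste(sort(unique(k)), collapse = "\r"), character(1))
        sig[as.integer(names(bySig))] <- bySig
    }
    none <- sig == ""
    sig[none] <- ifelse(stranded & oppCovered[none],
                        "opposite_strand\topposite_strand",
                        "intergenic\tintergenic")
    wBySig <- rowsum(w, sig)

    acc <- new.env(parent = emptyenv())
    acc$pairs <- numeric()
    acc$ambiguous <- 0
    for (i in seq_len(nrow(wBySig))) {
        keys <- strsplit(rownames(wBySig)[i], "\r", fixed = TRUE)[[1]]
        ww <- wBySig[i, 1]
        if (length(keys) == 1L) {
            .addPair(acc, keys, ww)
        } else if (ambiguityPolicy == "discard") {
            acc$ambiguous <- acc$ambiguous + ww
        } else {
            for (k in keys) .addPair(acc, k, ww / length(keys))
        }
    }

    new("FeatureCounts",
        sampleLabel = track@sampleLabel, depth = as.integer(depth),
        strandMode = track@strandMode, ambiguityPolicy = ambiguityPolicy,
        counts = .pairsToTable(acc$pairs, valueName = "count"),
        ambiguousDiscarded = acc$ambiguous,
        unmatchedChromDiscarded = unmatched,
        trackTotal = trackTotal(track))
}

# depth-d label keys ("category\tbiotype") of one gene at the positions p0;
# returns list(idx = indices into p0, key = label), one entry per label (a
# position with several labels appears several times). Deliberately
# re-derives the hierarchy rules from the raw records, independently of the
# token machinery in flatten.R.
.oracleGeneLabels <- function(g, p0, depth) {
    bt <- if (any(g$feature == "gene"))
        g$gene_biotype[g$feature == "gene"][1] else g$gene_biotype[1]
    covers <- function(feat) {
        r <- g[g$feature %in% feat, , drop = FALSE]
        m <- rep(FALSE, length(p0))
        for (j in seq_len(nrow(r)))
            m <- m | (p0 >= r$start[j] & p0 < r$end[j])
        m
    }
    n <- length(p0)
    key <- function(cat) paste(cat, bt, sep = "\t")
    if (depth == 1L)
        return(list(idx = seq_len(n), key = rep(key("gene"), n)))
    hasExons <- any(g$feature == "exon")
    if (!hasExons)
        return(list(idx = seq_len(n), key = rep(key("undescribed_gene"),
                                                n)))
    exonM <- covers("exon")
    if (depth == 2L)
        return(list(idx = seq_len(n),
                    key = ifelse(exonM, key("exon"), key("intron"))))
    cdsM <- covers(c("CDS", "stop_codon"))
    u5M <- covers("five_prime_utr")
    u3M <- covers("three_prime_utr")
    # bare "UTR" dialect: 5'/3' by position relative to the CDS span
    bare <- g[g$feature == "UTR", , drop = FALSE]
    cdsR <- g[g$feature == "CDS", , drop = FALSE]
    if (nrow(bare) && nrow(cdsR)) {
        bareM <- covers("UTR")
        before <- bareM & p0 < min(cdsR$start)
        after <- bareM & p0 >= max(cdsR$end)
        if (g$strand[1] == "-") {
            u5M <- u5M | after; u3M <- u3M | before
        } else {
            u5M <- u5M | before; u3M <- u3M | after
        }
    }
    startM <- covers("start_codon")
    stopM <- covers("stop_codon")

    idx <- which(!exonM)
    keys <- rep(key("intron"), length(idx))
    add <- function(mask, cat) {
        hit <- which(mask)
        idx <<- c(idx, hit)
        keys <<- c(keys, rep(key(cat), length(hit)))
    }
    l3sel <- exonM
    if (depth == 4L) {
        codon <- exonM & (startM | stopM)
        add(codon & startM, "start_codon")
        add(codon & stopM, "stop_codon")
        l3sel <- exonM & !codon
    }
    add(l3sel & cdsM, "CDS")
    add(l3sel & u5M, "five_prime_utr")
    add(l3sel & u3M, "three_prime_utr")
    add(l3sel & !cdsM & !u5M & !u3M, "undescribed_exon")
    list(idx = idx, key = keys)
}
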