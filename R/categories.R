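#' Category vocabulary
#'
#' Genomic categories are arranged in a containment hierarchy. Level 0 holds
#' the two strand-level categories (intergenic, opposite_strand), level 1 the
#' gene, level 2 its subdivision into exon/intron (or undescribed_gene when a
#' gene has no exon annotation), level 3 the exon subdivision into CDS and
#' UTRs (or undescribed_exon when an exon has no such children) and level 4
#' the start and stop codons.
#'
#' @return Named integer vector mapping each category name to its hierarchy
#'   level.
#' @examples
#' categoryLevels()[["CDS"]]
#' @export
categoryLevels <- function() {
    c(intergenic = 0L, opposite_strand = 0L,
      gene = 1L,
      undescribed_gene = 2L, intron = 2L, exon = 2L,
      undescribed_exon = 3L, CDS = 3L,
      five_prime_utr = 3L, three_prime_utr = 3L,
      start_codon = 4L, stop_codon = 4L)
}

# canonical display/sort order: by level, then fixed name order within level
.CATEGORY_ORDER <- c("intergenic", "opposite_strand",
                     "gene",
                     "exon", "intron", "undescribed_gene",
                     "CDS", "five_prime_utr", "three_prime_utr",
                     "undescribed_exon",
                     "start_codon", "stop_codon")

.GTF_FEATURES <- c("gene", "transcript", "exon", "CDS",
                   "five_prime_utr", "three_prime_utr", "UTR",
                   "start_codon", "stop_codon")

#' @keywords internal
.categoryRank <- function(category) {
    match(category, .CATEGORY_ORDER)
}

# parent of each depth-4/3/2 category when aggregating one level up the tree
.CATEGORY_PARENT <- c(start_codon = "CDS", stop_codon = "CDS",
                      CDS = "exon", five_prime_utr = "exon",
                      three_prime_utr = "exon", undescribed_exon = "exon",
                      exon = "gene", intron = "gene",
                      undescribed_gene = "gene")
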