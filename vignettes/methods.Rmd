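---
title: "Counting aligned nucleotides by genomic category and biotype"
author: "readscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting aligned nucleotides by genomic category and biotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readscape)
```

## The model

readscape answers one question about any aligned dataset: how are the
aligned *nucleotides* (not reads) distributed over the genome's functional
annotation? Counting nucleotides rather than reads makes the statistic
independent of read length, splicing structure and fragmentation, and lets
a single spliced read contribute to an exon and, through its gap,
contribute nothing to the intron it jumps.

Every genomic position carries, per gene covering it, an *annotation
chain* through the category hierarchy:

| level | categories | fallback when the chain stops here |
|------:|------------|------------------------------------|
| 1 | gene | — |
| 2 | exon, intron | `undescribed_gene` (gene record without exons) |
| 3 | CDS, five_prime_utr, three_prime_utr | `undescribed_exon` (exon without CDS/UTR children) |
| 4 | start_codon, stop_codon | the level-3 label |

Two strand-level categories complete the vocabulary: `intergenic`
(annotated on no gene) and, in stranded modes, `opposite_strand` (a read on
an unannotated strand facing annotation on the other strand). Each chain
also carries the gene's `gene_biotype`; the unit of counting is the joint
(category, biotype) pair. Reporting at depth *d* reduces each chain to its
deepest label at level ≤ *d*.

A position may carry several chains — two genes overlapping, or two
transcripts of one gene disagreeing (CDS in one, 3'UTR in another).
Identical labels deduplicate: a ten-transcript gene whose exon structure
agrees is not ambiguous. A position whose *reduced* label set at the
reporting depth has more than one element is **ambiguous at that depth**;
it is discarded and tallied by default, or its count is split equally
among the labels under the `split` policy. Ambiguity is evaluated at the
reporting depth, not at the deepest level: transcripts disagreeing only
about a codon do not contaminate a depth-3 run. (Whether a conflict below
the reporting depth should also discard is a genuinely open design point;
we chose reporting-depth evaluation because a conflict that is invisible
in the reported labels cannot change them.)

The **enrichment score** of feature *f* in sample *s* is

$$E_s(f) = \frac{n_s(f) \,/\, \sum_g n_s(g)}{L(f) \,/\, \sum_g L(g)},$$

raw fraction over genome fraction, so 1 means the sample follows the
genomic distribution. The raw-fraction denominator excludes
ambiguous-discarded nucleotides, so displayed fractions sum to 1; the
discarded percentage is reported separately on the message stream. The
enrichment is reported as the plain ratio (the definition is a division);
a log display is a plotting choice, not a different statistic.

## The three stages

**Indexing.** A GTF is an unordered, overlapping set of interval/feature
associations. `indexGtf()` flattens it once into non-overlapping intervals
each holding the complete set of annotation chains, in two variants: a
stranded index (per-strand annotation, enabling the opposite-strand rule)
and an unstranded index (per-position union of both strands). Features on
strand "." are placed on both strands. The index is a deterministic
function of the GTF — byte-identical files on every rebuild — and stores
the GTF's md5 digest so a rerun can detect staleness and reuse it.

**Counting.** Coverage comes from BAM (via `GenomicAlignments`, with
split-read semantics: CIGAR M/=/X and D cover the reference, N gaps do
not, insertions and clips contribute nothing; secondary and supplementary
alignments are excluded) or from existing bedgraph tracks. Strandness
reflects the library protocol: `forward` keeps a single-end read's
alignment strand, `reverse` flips it, and for paired-end data mate 1
defines the fragment strand with mate 2 flipped before the mode applies
(a convention; mates with inconsistent flags are skipped with a tally in
stranded modes). The intersection itself never loops over positions: both
the coverage track and the index are sorted disjoint interval lists, so a
vectorized interval join (a `findInterval`-based sweep) splits each
coverage interval against the index and accumulates `width x depth` per
annotation — equivalent, provably and testedly, to classifying every
nucleotide independently.

**Reporting.** Counts marginalize to the category axis and the biotype
axis; each yields a two-panel figure (raw fractions, enrichment) with
grouped bars per sample. The numbers behind every figure are written to a
`*.plotdata.tsv` sidecar, which is the testable surface of the plot —
image bytes depend on the graphics stack, the sidecar does not.

## Parameters that matter

* `depth` (1–4, default 3): reporting depth. Depth 4 exposes start/stop
  codons, e.g. for ribosome-profiling initiation shifts; depth 1 gives the
  classic genic/intergenic/opposite-strand triage.
* `strandness` (`unstranded` default, `forward`, `reverse`): must match
  the library protocol, otherwise sense and antisense signal swap.
* `ambiguity` (`discard` default, `split`): `discard` is conservative and
  keeps counts integral; `split` conserves total signal at the cost of
  fractional counts.
* `minMapq` (0): alignment filtering belongs upstream; by default every
  primary alignment counts once, duplicates and multimappers included.
* chromosome lengths: a GTF carries none, so intergenic extent beyond the
  last feature is unknowable from the annotation alone. Lengths are taken
  from the BAM header at categorization time; for bedgraph input they fall
  back to the larger of the annotation and track extents unless supplied.
  Chromosomes present in a sample but absent from the annotation are
  skipped with a warning and tallied, never silently counted; name
  matching is exact (no chr1/1 aliasing).

## Numerical and degenerate-input choices

All internal coordinates are 0-based half-open, converted exactly once at
each I/O boundary (GTF and SAM are 1-based inclusive, bedgraph is 0-based
half-open); this removes the off-by-one class entirely, and the
acceptance sweep would catch any relapse. Counts accumulate in double
precision; in discard mode with integer depths every tally is exact
(integer-valued doubles), and conservation — assigned + ambiguous +
unmatched = track total — is asserted exactly there and to 1e-9 under
`split`. Stop codons, which Ensembl excludes from the CDS, carry the
level-3 label CDS so that depth-3 output does not show a 3 nt
"undescribed" sliver per gene. Bare `UTR` features (the pre-release-75
GTF dialect) are assigned 5'/3' by their position relative to the gene's
CDS span on its strand, and contribute nothing when the gene has no CDS.
A child feature extending outside its gene record extends the effective
gene span with a warning rather than failing: real annotations contain
such records. A missing `gene_biotype` becomes the biotype
`"undescribed"`, extending the annotation's own "undescribed" device to
the biotype axis. Transcript records only group children; there is no
"transcript" category.

## What the synthetic data emulates — and what it does not

The fixture module generates miniature genomes (1–2 chromosomes of
0.6–2.5 kb, up to a handful of genes) whose structures deliberately cover
the awkward cases: overlapping genes on the same and opposite strands,
gene-only records, transcripts that disagree at level 3, bare-UTR
dialect, children outside the gene span, missing biotypes, strandless
features, spliced reads, and chromosomes with reads but no annotation.
Read sets are placed uniformly (or planted region-by-region with exact
nucleotide totals when a scenario needs known signal). Sizes were chosen
so the whole acceptance sweep — 200 random genomes, every strand mode,
depth and policy, each compared against a brute-force per-nucleotide
oracle — runs in a few minutes; the per-genome scale does not affect what
is being proven, since the oracle equivalence is exact at any size.

What the toys do *not* emulate: realistic read-length and quality
distributions, mapping error, duplicate structure, chained
multi-exon-spanning CDS records split across many lines, or
genome-sized annotations. Passing tests therefore certify the counting
semantics, not the runtime behavior on a 3 Gb genome or robustness to
malformed real-world GTF excentricities beyond those listed.

## The independent oracle

`oracleCounts()` re-derives the whole semantics naively: it expands the
coverage into individual positions and labels each one by scanning every
GTF record directly — no flattened index, no interval arithmetic — then
applies the same depth reduction and ambiguity policy. It shares no
classification code with the fast path (only the GTF parser and the final
table container), is O(positions × records), and is guarded to toy scale.
The equivalence suite asserts exact agreement in discard mode and 1e-9
agreement in split mode across randomized genomes, which is the package's
strongest correctness argument.

## Known limitations

Nucleotide-level counting cannot substitute for gene-level
quantification: the output is a genome-scale overview, blind to effects
confined to a small fraction of the data, and unsuitable for differential
analysis per gene. GFF3 is not parsed (GTF only). CRAM is not read.
Coverage is raw — no RPKM-style normalization, by design, since the
enrichment score already normalizes by feature size. The paired-end
mate-strand convention and the reporting-depth ambiguity evaluation are
documented choices that other tools may make differently.
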