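---
title: "Finding dispersed repeats in organelle genomes"
author: "OrganelleRepeats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding dispersed repeats in organelle genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(OrganelleRepeats))
```

## The problem

Plant mitochondrial genomes — and organelle genomes generally — carry
families of non-tandem ("dispersed") repeats: two or more near-identical
sequence copies at separated locations, in either orientation, ranging
from tens of base pairs to tens of kilobases.  The large ones mediate
homologous recombination that isomerizes the genome; the intermediate
ones recombine under stress or in repair mutants.  Because copies are
kept identical by gene conversion, recently active repeats are exact or
nearly exact duplicates, and a deliberately *stringent* alignment
criterion is the right detector: it finds the recently created or
recently converted copies while ignoring ancient diverged paralogy.

This package finds those repeats in a single pass over one genome
sequence, curates them into distinct families with every copy located,
and summarizes repeat size spectra within and across genomes.  It is a
reimplementation of a BLAST-pipeline approach as a self-contained exact
algorithm, so results are deterministic and reproducible without an
external aligner.

## The method

For a genome $G$ of length $L$ the engine finds all ungapped local
self-alignments on both strands:

1. **Seeding.** Every word of length $w$ (default $w = 50$) is indexed;
   a seed is a pair of positions sharing a word exactly, on the same
   strand or between the forward strand and the reverse complement.
   Seeds on one (anti)diagonal belonging to one maximal exact run are
   coalesced into a single seed, so a long exact duplication costs one
   extension rather than thousands.  The trivial self-match of each
   position with itself (the "full-length self-identity") is excluded
   by construction.
2. **Extension.** Each seed run is extended outward along its diagonal
   under match reward $r = +1$ and mismatch penalty $p = -20$.
   Extension is X-drop limited: scanning stops when the running score
   falls more than $X$ below the best score seen (default
   $X = 2\,|p| = 40$), and the reported segment ends at the farthest
   position attaining the best score, so equal-scoring alternatives
   resolve to the *longest* segment.  Masked residues and sequence ends
   are hard barriers.
3. **Reporting.** A segment is reported when its score
   $r\,(\mathrm{len}-\mathrm{mm}) + p\,\mathrm{mm}$ reaches the minimum
   score (default $w \cdot r$).  Each unordered interval pair appears
   once, in a canonical orientation.

**Why X-drop, and why $X = 2|p|$.**  With $p = -20$, crossing a single
mismatch costs 20 matches; an isolated substitution inside a long
duplication should not fragment it, so extension must be able to cross
one or two mismatches and recover.  A *cluster* of three or more
consecutive mismatches at the center of a duplication is different: it
is evidence of two independent duplication events (or escape from gene
conversion), and the method deliberately reports two shorter repeats
rather than one long diverged one.  $X = 2|p|$ is the smallest
threshold with exactly this behavior: one mismatch (drop $|p|$) is
always crossable, and three consecutive (drop $3|p| > X$) always
terminate extension.  A fully score-optimal extension would instead
merge the two halves whenever each half is longer than $|p|$ matches,
which is the wrong biology here; a never-cross-a-mismatch rule (what a
default-configured BLAST effectively does at these scores, where the
bit-scaled drop-off is smaller than one mismatch penalty) would report
only maximal exact matches and fragment singly-diverged copies.  The
X-drop is exposed as a `ScoringScheme` parameter for users who want
either extreme.

**The E-value surrogate.**  A BLAST-based pipeline reports everything
under a very permissive E-value; that knob has no closed form here.
Because any alignment with score $\ge w$ under $+1/-20$ scoring
necessarily contains an exact core of at least word size, the minimum
score (default $w \cdot r = 50$) is the faithful, implementable
reporting threshold.

## Curation into families

Raw alignments list each repeat pair twice (query/subject exchanged)
and, for families with three or more copies, only a subset of pairwise
hits is needed to recover the family.  Curation proceeds exactly as the
classic pipeline does, by coordinates rather than by sequence
clustering:

1. duplicate and reciprocal listings are removed
   (`deduplicateHsps()`);
2. one representative sequence per distinct repeat is extracted,
   collapsing content-identical and reverse-complement-identical
   candidates (`selectRepresentatives()`);
3. each representative is re-queried against the whole genome on both
   strands (`locateAllCopies()`): a location is a copy when the
   alignment covers the representative *full-length* with at most one
   mismatch per 100 bp (`tolerancePer100`, matching the scoring's
   break-even where one mismatch costs 20 matches).  Full-length
   coverage preserves the premise that all copies of a family share a
   single length — the property that makes coordinate-based curation
   reliable under penalties of $-18$ and below;
4. families whose copy *interval sets* coincide, or same-length
   families sharing a copy interval, are merged.  Copy orientation is
   relative to the representative (a family planted entirely on the
   minus strand is indistinguishable from its plus-strand mirror), so
   intervals, not strands, define copy identity during merging.

Families are labelled `R1, R2, ...` by descending length.  Tandem
arrays (any two copies overlapping or abutting) are detected, kept and
flagged rather than removed — some gymnosperm mitochondria carry many
tandemly repeated elements and silently dropping them would be wrong.
A perfect palindrome appears as a minus-strand self-match with
identical query and subject intervals and surfaces as a two-copy family
at one location on opposite strands, flagged tandem by the overlap
rule.

## Coordinates and output

All coordinates are 1-based inclusive throughout, the convention shared
by GenBank, BLAST tabular output and the Bioconductor `IRanges` stack;
there is no internal half-open representation to convert at the
boundary.  Outputs per genome: repeat FASTA (representatives with
family id, length, copy number), a per-copy TSV table with per-genome
summary statistics, a binned size table, and an NCBI 5-column feature
table (`repeat_region` with `rpt_type dispersed`, minus-strand copies
encoded by start > end) suitable for GenBank submission — chosen as the
standard annotation dialect since nothing more specific is mandated.
Output ordering is deterministic (length desc, first-copy start,
sequence), so repeated runs are byte-identical.

## Size bins and group summaries

The binned size table uses right-open bins with default edges 50, 100,
200, ..., 900, 1000, 2000, ..., 10000 (last bin unbounded).  The edges
are configurable; the defaults span the observed range in green-plant
mitochondria, from the 50 bp detection floor to the >10 kb repeats of
vascular plants, with finer resolution below 1 kb where the
biologically distinct size classes live.  A repeat of exactly 200 bp
counts in the bin *starting* at 200 ("repeats greater than 200 bp" in
the field's phrasing).  Across a genome collection, the group summary
reports, per taxonomic group and size bin, the fraction of species with
at least one family in that bin — always $k/n$ with $k$ an integer
count of species — which normalizes away the order-of-magnitude
differences in per-species repeat counts.

## The synthetic generator and what tests show

`generateBackground()` draws i.i.d. sequence at a configurable GC
(default 0.45, typical of plant mtDNA) and verifies that no word of the
seed length occurs twice in either orientation — at $4^{-50}$ collision
rates this never triggers in practice, but it makes planted truth sets
exact by construction.  `plantFamilies()` writes families of chosen
length, copy number, orientation and per-copy substitutions, and
resamples the bases flanking each copy so that every pairwise copy
alignment terminates exactly at the planted boundaries.  That flank
sharpening matters: without it, any local aligner (this one or BLAST)
extends a repeat by however many flanking bases happen to match by
chance, and "exact length recovery" would be ill-posed.  Planted
substitution positions drawn by count are kept at least ~25 bp from the
copy ends for the same reason — a substitution closer to the end than
the score needed to cross it is trimmed by *any* score-based aligner
and belongs to a boundary-effect test, not a recovery test.

The generator emulates: neutral background, exact and diverged copies,
both orientations, tandem adjacency, and mismatch clusters.  It does
not emulate real organelle features — gene content, GC skew, short
tandem microsatellites, low-complexity tracts, or gapped divergence
(indels) between copies.  Passing the synthetic suite therefore
demonstrates correctness of the algorithm on its stated model, not
robustness to, say, indel-diverged families, which an ungapped method
intentionally reports as split repeats.

A brute-force oracle (`oracleSelfCompare()`) re-derives the full
alignment set by scanning every diagonal and antidiagonal with scalar
stepping, independently of the seed index machinery; engine/oracle set
equality is asserted over 100 random planted fixtures of 2-10 kb per
test run.  Whole-genome validation sizes were chosen to keep the
quadratic oracle affordable: equality checks run at up to 10 kb,
random-null checks at 100 kb over 5 seeds, both far above the scale at
which seeding or coalescing edge cases could hide.

## Circular genomes

Circular mode (off by default — linear is the common deposited form)
conceptually doubles the sequence, discards alignments whose query
starts beyond the original length or that exceed it, removes the
junction self-identity diagonal, and reduces subject coordinates modulo
the length.  A copy spanning the origin is reported with its end beyond
the genome length, denoting wrap-around.  Sub-alignments of a wrapped
repeat that are also visible in the linear sequence remain in the
output as separate (shorter) entries; users analyzing a known-circular
molecule should inspect the longest call per locus.

## Parameters at a glance

| parameter          | default          | meaning                                         |
|--------------------|------------------|-------------------------------------------------|
| `wordSize`         | 50 bp            | exact seed length; detection floor               |
| `matchReward`      | +1               | per-column match score                           |
| `mismatchPenalty`  | -20              | per-column mismatch score; $\le -18$ keeps copy lengths equal |
| `minScore`         | `wordSize`       | reporting threshold (E-value surrogate)          |
| `xDrop`            | `2*abs(penalty)` | extension drop-off; crosses 1-2 mismatches, splits at 3+ consecutive |
| `tolerancePer100`  | 1                | second-pass copy acceptance, mismatches per 100 bp |
| `binEdges`         | 50...10000       | right-open size bins                             |

Penalties above $-18$ are accepted (for close examination of a single
genome) but produce a warning: copies of a family may then differ in
length and the coordinate-based curation loses its footing.

## A worked example

```{r example}
bg <- generateBackground(20000, gc = 0.45, seed = 11)
pf <- plantFamilies(bg, list(
  plantSpec(600, 3, c("+", "+", "-")),
  plantSpec(250, 2, mismatches = list(integer(0), c(80L, 200L)))),
  seed = 12)
fams <- findRepeats(pf$genome)
for (f in fams) show(f)
genomeRepeatTable(fams, pf$genome)$summary
binRepeats(fams)[binRepeats(fams)$count > 0, ]
```

## Known limitations

* Ungapped only: an indel between copies splits a family in two, by
  design; there is no gapped mode.
* Heuristics for chromosome-scale (>10 Mb) inputs are out of scope; the
  engine is exact and sized for organelle genomes (up to ~1 Mb).
* Multi-record FASTA input is rejected: inter-chromosomal repeats add a
  complexity layer the curation model does not cover.
* The boundary of a repeat whose copies diverge *at* the ends is
  trimmed to the best-scoring extent; against a heuristic aligner's
  output, boundary positions may differ by a few base pairs at repeat
  edges even when the repeat set is identical.
* IUPAC ambiguity codes are either rejected (default) or masked;
  masked positions can never match, including against themselves.
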