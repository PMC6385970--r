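# OrganelleRepeats

Discovery, curation and size-spectrum analysis of non-tandem
(dispersed) repeats in organelle-scale genome sequences — the repeat
families of plant mitochondrial genomes that mediate recombination,
genome isomerization and structural evolution.

Dispersed repeats in plant mitochondria are kept identical by gene
conversion while they are recombinationally active, so a stringent,
ungapped alignment criterion detects exactly the biologically
interesting set: recently created or recently converted copies.
`OrganelleRepeats` implements that criterion as a self-contained exact
algorithm, for anyone who needs reproducible repeat catalogs from
single-molecule organelle assemblies (15 kb to ~1 Mb): comparative
organelle genomics, mitochondrial genome assembly QC, or annotation of
`repeat_region` features for database submission.

## The method

For a genome of length *L*, all ungapped local self-alignments on both
strands are found by exact seeding and bounded extension:

* **Seeds** are exact shared words of length *w* (default *w* = 50),
  on the same strand or between the forward strand and the reverse
  complement, coalesced per maximal exact run on each (anti)diagonal.
* **Extension** uses blastn-style scoring (match +1, mismatch −20 by
  default) with an X-drop bound: scanning stops when the running score
  falls more than *X* = 2·|penalty| below the best seen, and the
  segment ends at the farthest position attaining the best score
  (ties resolve to the longest).  An isolated substitution inside a
  duplication is crossed; a cluster of ≥3 consecutive mismatches
  splits the duplication into two repeats — deliberate, since central
  divergence marks two independent events.
* **Reporting** requires score ≥ *w*·(match reward), the implementable
  surrogate for a permissive E-value threshold: with +1/−20 scoring
  any reported alignment necessarily contains a word-size exact core.
* **Curation** removes reciprocal listings, extracts one representative
  per distinct repeat, re-queries each representative against the
  whole genome to locate *every* copy (full-length coverage, at most 1
  mismatch per 100 bp), merges families by copy intervals, and labels
  them R1, R2, ... by descending length.  All copies of a family share
  one length; tandem arrays are flagged, not dropped.

Summaries: per-genome copy tables, right-open size bins
(50, 100, 200, ..., 1000, 2000, ..., 10000+ bp), batch processing of
genome directories, and the per-taxon-group fraction of species with
at least one repeat per size bin.

A synthetic-genome generator with planted repeat families of known
length, copy number, orientation and divergence — plus a brute-force
alignment oracle — provides exact ground truth for the test suite.

## A worked example

```r
library(OrganelleRepeats)

bg <- generateBackground(20000, gc = 0.45, seed = 11)
pf <- plantFamilies(bg, list(
  plantSpec(600, 3, c("+", "+", "-")),
  plantSpec(250, 2, mismatches = list(integer(0), c(80L, 200L)))),
  seed = 12)

fams <- findRepeats(pf$genome)
for (f in fams) show(f)
#> RepeatFamily R1: 600 bp, 3 copies
#> RepeatFamily R2: 250 bp, 2 copies

genomeRepeatTable(fams, pf$genome)$summary
#>   genome_id genome_bp n_families largest_bp repeated_bp fraction_repeated
#> 1 synthetic     20000          2        600        2300             0.115
```

The 600 bp family is recovered with all three copies (one inverted,
strand `-`); the 250 bp family's second copy carries the two planted
substitutions, recorded in its copy table row (`mismatches = 2`):

```r
genomeRepeatTable(fams, pf$genome)$copies
#>   family_id length copy_count copy_index start   end strand mismatches tandem
#> 1        R1    600          3          1  4569  5168      +          0  FALSE
#> 2        R1    600          3          2 10167 10766      -          0  FALSE
#> 3        R1    600          3          3 11458 12057      +          0  FALSE
#> 4        R2    250          2          1  1770  2019      +          0  FALSE
#> 5        R2    250          2          2 13489 13738      +          2  FALSE
```

On real data: `readGenome("genome.fasta")` then `findRepeats()`, or
use the command line driver
(`system.file("scripts", "orgrep.R", package = "OrganelleRepeats")`):

```sh
Rscript orgrep.R find mito.fasta -o results/mito       # one genome
Rscript orgrep.R batch genomes/ -o results/            # a directory
Rscript orgrep.R groups results/combined_bins.tsv --map groups.tsv
Rscript orgrep.R synth --length 50000 --plant 600,3,++- -o fixture
```

`find` writes the repeat FASTA, per-copy TSV, binned-size TSV, an NCBI
5-column feature table ready for GenBank annotation, and a manifest
that reproduces the run.

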