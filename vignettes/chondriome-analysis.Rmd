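---
title: "Comparing heteroplasmic mitochondrial genomes with chondriomics"
author: "chondriomics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing heteroplasmic mitochondrial genomes with chondriomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chondriomics)
```

## The problem

Plant mitochondrial genomes are large (hundreds of kb), circular in their
conventional representation, and rarely homogeneous within a cell: the
chondriome is usually a stoichiometric mixture of related genome variants
(*mitotypes*) differing by substitutions, segment inversions and deletions.
This heteroplasmy matters most in *alloplasmic* lines — plants carrying the
nucleus of one species on the cytoplasm of another — where disrupted
nuclear–mitochondrial interactions are associated with cytoplasmic male
sterility (CMS), rapid structural rearrangement, substoichiometric shifting
of mitotypes, and the emergence of novel, often chimeric, open reading
frames.

`chondriomics` implements the comparative analyses such a study needs, as
testable, reusable functions:

1. **Heteroplasmy detection** — per-position base counts from aligned reads,
   a coverage mask, heteroplasmic SNP (HSNP) calling by a minor-allele-read-
   fraction rule, and clustering of HSNPs into high-density blocks.
2. **Consensus-genome comparison** — homologous-region detection at a 95%
   identity cutoff, inter-genome substitution SNPs, coding-change annotation
   in start-codon-relative notation (e.g. `E/A^57`), frameshift/premature-stop
   analysis, and the assembly contig-join rule.
3. **Gene-order analysis** — signed circular gene orders, conserved pairs and
   synteny blocks, and breakpoint (rearrangement) distance.
4. **ORF analysis** — six-frame circular ORF scanning, species-uniqueness by
   homologous coverage, and decomposition of chimeric ORFs into donor-gene
   fragments.
5. **A synthetic chondriome simulator** providing complete ground truth for
   all of the above.

## Decision rules and their thresholds

All numeric rules live in one object so a report can state exactly what it
was produced under:

```{r}
str(unclass(analysis_thresholds()))
```

* `min_depth = 10` (reads). Positions covered below 10x are excluded from
  SNP analysis entirely; the boundary is inclusive (depth 10 passes). The
  excluded genome space is reported as a coverage mask (BED).
* `min_minor_frac = 0.10`, **strict**. A heteroplasmic SNP requires a single
  minor allele carried by *more than* 10% of the reads: 1 of 10 reads (10%)
  is not a call, 3 of 20 (15%) is. The rule is per-allele: two rare alleles
  jointly above 10% do not trigger a call; this is the conservative reading
  and is monotone in both thresholds (tested). Indels never trigger a call;
  reads deleted at a position count toward depth but toward no allele.
* `block_min_count = 3`, `block_max_gap = 150` bp. HSNP blocks are greedy
  left-to-right chains of calls at most 150 bp apart, kept when they have at
  least 3 members; everything else is a singleton. The source analysis never
  formalised block boundaries, so these two parameters are explicit and
  configurable; the defaults give block/singleton partitions of the same
  shape as published distributions.
* `homology_min_identity = 0.95`, inclusive. Homologous regions between
  consensus genomes are retained at identity ≥ 0.95 and length ≥ 200 bp
  (50 bp when the query is a single ORF).
* `orf_min_len = 300` bp, stop codon included.
* `orf_unique_max_cov = 0.95`. An ORF is species-unique when homologous
  alignments against *every* other genome cover at most 95% of its length —
  96% coverage anywhere disqualifies it.
* `join_min_overlap = 100` bp (strict) and `join_max_dissim = 0.01`. Contigs
  are joined only on a suffix/prefix overlap of *more than* 100 bp with less
  than 1% dissimilarity, where gap columns count as differences
  (conservative).

Ties between equal base counts are broken alphabetically (A < C < G < T),
making every call deterministic.

## Coordinate conventions

Internally everything is 0-based, half-open, and modulo the genome length;
1-based coordinates appear only in human-facing formats (VCF, GFF3) and in
the start-codon-relative variant notation (`A/C^170` means position 170 of
the coding sequence, codon `ceiling(170/3) = 57`). Intervals that wrap the
origin are written with `end > genome length`.

SAM has no native circular convention, so truth alignments are emitted
against the linearised reference and reads wrapping the origin are split
into records sharing a read name. The same convention covers reads crossing
a reversal boundary (strand changes mid-read); reads spanning a mitotype
deletion carry a `D` CIGAR operation instead.

## The simulator: what it emulates, and what it does not

`generate_master()` builds a random circular genome with non-overlapping
protein-coding genes (ATG start, in-frame stop, no internal stop, both
strands) and repeat families placed verbatim at two loci — the long repeats
through which plant mitochondrial genomes recombine. `derive_mitotype()`
applies substitutions, in-place segment reversals and deletions, recording
every edit; replaying the edit list reproduces the mitotype byte-for-byte
(a tested invariant). Edit intervals must be disjoint and may not wrap the
origin; substitutions are placed outside structural edits so that their
master coordinates are also alignment coordinates, keeping the heteroplasmy
truth table exact.

`simulate_reads()` emulates 454 GS FLX-style single-end shotgun data: read
lengths are truncated-normal (mean 449 bp, bounds 100–1000 bp, matching the
platform's range), each read is drawn from a mitotype with probability equal
to its stoichiometric fraction, and substitution errors hit each base
independently, uniformly over the three alternative bases. Homopolymer
indel errors — the platform's characteristic artifact — are off by default
because the downstream caller ignores indels by design; a non-zero
`indel_error` exists purely to stress the pileup builder and is not covered
by truth CIGARs. There is no flowgram/quality model and no chimeric-read
artifact. Consequently, passing recovery tests demonstrate that the caller
implements its stated rules exactly under binomial sampling and uniform
error; they do not demonstrate robustness to mapping artifacts,
context-dependent error, or reference bias in real 454 data.

Default scenario: a 50 kb master (a deliberate desk-scale stand-in for the
~400–450 kb genomes the analysis targets), 30 genes, two 1 kb repeat
families, two mitotypes at 0.8/0.2 differing by 200 substitutions, 100x
coverage, 1% error. The mitotype count and fractions are a scenario choice —
no published line states its true mixture — and sit in the regime where a
0.2 minor mitotype is comfortably above the 10% calling threshold at 100x.

## Statistical behaviour worth knowing

**Minor-fraction noise floor.** At depth $d$ the minor-allele read fraction
at a truly heteroplasmic site is a binomial proportion with standard error
$\sqrt{p(1-p)/d}$ — 0.04 for $p = 0.2$ at 100x. The mean absolute error of
the per-site estimate is therefore $\sqrt{2/\pi}\,·\,0.04 \approx 0.032$
*for any correct caller*; sequencing error adds slightly more. Averaging
minor fractions across all HSNPs of a mitotype estimates its stoichiometry
far more precisely (SE $\approx 0.04/\sqrt{n_\text{sites}}$).

**False-positive calibration.** On a homoplasmic simulation the number of
HSNP calls has a closed-form expectation: with per-base error $e$ uniform
over three alternatives, a column of depth $d$ triggers a call with
probability $1 - (1 - P[X > \lfloor 0.1d \rfloor])^3$, $X \sim
\mathrm{Binom}(d, e/3)$. The calibration experiment uses an elevated error
(5%) at 25x so this expectation is resolvably non-zero (~1,400 calls across
50 kb rather than ~$10^{-12}$ at 1%/100x); observed counts agree within
sampling noise, which is the package's analogue of estimating a
false-positive rate over conserved gene space.

## Numerical and algorithmic choices

* **Homology search** is seed-and-extend: exact 15-mer anchors (a
  `data.table` join), merged into diagonal runs (gaps ≤ 50 bp on a
  diagonal), chained across small diagonal shifts (band 50, gap ≤ 300 bp),
  and stitched into gapped alignments with Needleman–Wunsch on the
  inter-anchor gaps (match 1, mismatch −2, gap open 5, extend 2). Full DP on
  two 50 kb genomes is infeasible; on sequences ≤ 2 kb the stitched identity
  agrees with full dynamic programming within 0.005 (tested). The subject is
  doubled to catch origin-crossing homology; duplicates are removed after
  reducing coordinates modulo the length. Alignments crossing the *query's*
  origin are reported as two pieces.
* **Breakpoint distance** operationalises "recombination/rearrangement
  events": the number of signed, cyclic gene adjacencies of one order absent
  from the other, computed on the induced subpermutation of shared genes
  (genes private to one genome, e.g. lost genes, are dropped first).
  Identity gives 0, one reversal 2, one transposition 3; the count is
  symmetric and invariant under rotation and global strand flip (all
  property-tested, plus exhaustive agreement with a naive adjacency-set
  oracle over every signed circular permutation of up to 7 genes). Published
  event counts obtained by eye from synteny figures need not equal this
  distance, and reproducing any specific published integer is a non-goal;
  the distance is reported alongside as `events_estimate`. Synteny blocks
  are computed on the circle, so two collinear runs that meet across the
  origin merge into one block — a linear reading of the same orders would
  split them.
* **Multi-copy genes** (e.g. rRNA repeats) are disambiguated
  deterministically by coordinate order with `-1`, `-2` suffixes;
  alternative copy matchings are out of scope.
* **ORF scanning** requires an ATG start and a standard-code stop, reports
  the longest ORF per stop codon and frame (nested later starts are
  suppressed, the behaviour of standard ORF finders), permits a single wrap
  of the origin, and includes the stop codon in the reported length — the
  300 bp minimum is inclusive. When the genome length is not a multiple of
  3, a stop reached across the origin can be indexed in two linear frames of
  the doubled sequence; grouping stops modulo the genome length merges these
  correctly (a bug class the brute-force oracle test catches).
* **Chimera decomposition** collects local alignments of an ORF against a
  donor-gene database (both strands, recursing into unmatched flanks so
  multiple fragments of one donor are found) and tiles them greedily by
  descending score into non-overlapping query segments; a lower-scoring
  segment overlapping a chosen one is trimmed to the uncovered run and kept
  only if it still reaches `min_segment` (30 bp at ≥ 90% identity by
  default). Ties break toward the longer segment, then lexicographic gene
  id. Uncovered query intervals are reported as unassigned rather than
  silently dropped.
* **Degenerate inputs** are values, not crashes: zero HSNPs yields an
  undefined (`NA`) per-bp density rather than a division error; a refused
  contig join explains which rule failed; an empty annotation set gives an
  empty gene order; fewer than two shared genes is a rejection for distance
  computation.

## Test and simulation sizes

The packaged tests run the full recovery analysis on a 50 kb chondriome at
100x (~11,000 reads), the false-positive calibration at 25x, 100 random 5 kb
circles against the brute-force ORF oracle, and the exhaustive breakpoint
enumeration to 7 genes (~100,000 signed circular permutations). These sizes
were chosen so the whole suite completes in a few minutes while every
statistical check retains enough resolution to fail loudly if a rule drifts
by one read or one base pair.

## Known limitations

* No read mapping is included; alignments come from the simulator's truth
  SAM or an external mapper. Pileup semantics (depth = CIGAR ops consuming
  reference; soft clips ignored; ambiguous bases in depth but not counts)
  are declared rather than inherited from any specific mapper.
* The HSNP caller is exactly the stated threshold rule — no statistical test
  of heteroplasmy, no phasing of HSNPs into mitotypes.
* Consensus comparison assumes one designated representative sequence per
  genome; allele-abundance-aware comparison of multi-copy genes is not
  modelled.
* Reversal distance in the Hannenhalli–Pevzner sense, repeat-mediated
  recombination inference, and database novelty searches for ORFs are out of
  scope.
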