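---
title: "Methods: inverted-repeat detection, positional statistics, and nucleosome occupancy in irscape"
author: "irscape"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: inverted-repeat detection, positional statistics, and nucleosome occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irscape)
```

# Scope and model

irscape implements a genome-wide analysis of perfect inverted repeats (IRs)
with cruciform-forming potential. An IR is a DNA segment whose two arms
(repeat units) of length $R$ are exact Watson–Crick reverse complements of
each other, separated by a spacer of length $S$; such a segment reads
identically 5'→3' on both strands and, under negative supercoiling, can
extrude into a four-way cruciform whose stem is the arm and whose loop is
the spacer. The detection thresholds are the cruciform-competence window
established for short stems: $R \ge 5$ bp, $0 \le S \le 8$ bp and total
length $2R + S \ge 13$ bp. Imperfect (mismatched) repeats are outside scope:
they are rarer, mutate toward perfection, and need more energy to extrude.

The analysis has five computational stages, each an exported function
family:

1. **Detection** (`findMaximalIRs`) — all maximal perfect IRs above the
   thresholds, each mapped to the single genomic position of its central
   base.
2. **Classification** (`classifyIRs`) — seven sequence types from three arm
   predicates.
3. **Partition and anchoring** (`partitionGenome`, `relativeOffset`,
   `lengthGroups`) — genic/intergenic region classes anchored at the TSS,
   start codon (first base), stop codon (third base) and poly(A) site, each
   defined as offset 0.
4. **Positional statistics** (`profileWithControls`) — IR-center counts in
   10-bp bins against 100 composition-preserving randomized genomes, with a
   per-bin Grubbs outlier call.
5. **Chromatin** (`nnuocProfile`) — chromosome-normalized binary nucleosome
   occupancy (nNuOc) averaged in ±200-bp windows around IR centers.

A sixth stage, the synthetic-genome generator (`generateSyntheticGenome`),
is first-class tested code: it emulates the statistical structure the
analysis assumes so that every stage is verifiable without external
downloads.

# Detection

## Algorithm

For every spacer size $S \in \{0..8\}$ and every spacer placement, the two
arms are extended outward while the flanking bases pair (A:T, G:C only; `N`
pairs with nothing, so arms never cross it). This inner loop is compiled
(Rcpp); the cost is $O(9 L \bar{e})$ for genome length $L$ and mean
extension depth $\bar{e}$, a few tens of milliseconds per megabase, which
matters because every profiling run re-scans 100 randomized genomes.
Candidates passing the thresholds then go through containment pruning:

* a record whose interval is a **proper sub-interval** of another's is
  removed (when an IR lies inside a larger IR only the outer one is kept);
* among records with the **same interval** but different $(R, S)$
  decompositions (e.g. `AAAAAAATTTTTTT` reads as R7S0, R6S2 or R5S4),
  exactly one is kept: largest arm, then smallest spacer. The outer-IR rule
  does not address this case; we keep the largest stem because stem length
  dominates cruciform energetics.
* **overlapping but non-nested** IRs are all kept — only containment is
  pruned.

Maximality is guaranteed by construction (extension stops only at a
non-pairing flank or the sequence end) and is asserted property-style in the
tests, together with exact equality against an independent brute-force
enumeration of every $(start, R, S)$ triple on ~1,000 random sequences and
strand symmetry (the scanner applied to the reverse complement yields
mirrored intervals).

## Coordinates and the center base

Internally all coordinates are 1-based inclusive, the GRanges/Biostrings
convention, so every interval shown by an `IRSet` can be used directly with
other Bioconductor tooling; BED export converts to 0-based half-open, GFF3
stays 1-based. An IR of even total length has no central base; we take the
left-of-middle base, `center = start + (width - 1) %/% 2`. All downstream
positional statistics use only this one base per IR.

# Classification

Three quantities are computed on the 5' arm only (the spacer is not part of
the repeat unit):

* **AT content** — fraction of A+T bases. Threshold 0.6, chosen just below
  the *S. cerevisiae* genome-wide AT content of 0.62, so "AT-rich" means
  at least genome-average composition.
* **Tract occupancy** — longest run of A's or of T's with run length ≥ 3,
  divided by arm length (0 if no such run). Threshold 0.5.
* **Alternating occupancy** — longest substring of the exact form
  $(AT)_n$ or $(TA)_n$, $n \ge 1$, divided by arm length. Alternating
  stretches are counted in complete dinucleotide units, so `ATA` scores 2,
  not 3. Threshold 0.5.

The three booleans map onto seven types: AT-rich arms split into I (tract-
and alternating-rich), II (tract-rich), III (alternating-rich), IV
(neither); non-AT-rich arms split into V (tract-rich), VI
(alternating-rich, absorbing both tract states) and VII (none of the
three). Types I, II, III, V and VII follow their published verbal
definitions exactly; **the assignments completing the table — IV by
elimination within the AT-rich block, and VI absorbing the two non-AT-rich
alternating-rich combinations so that exactly seven types result — are
inferred, not published**, and are therefore isolated behind
`classifyArmFeatures` with all three thresholds exposed as arguments.
Classification is arm-symmetric: the right arm is the reverse complement of
the left, which maps A-tracts to T-tracts and $(AT)_n$ to $(TA)_n$, and
every predicate is an "A or T" disjunction.

# Genome partition and anchoring

Gene models carry four anchors: TSS, first base of the start codon, third
base of the stop codon, and poly(A) site (1-based in the annotation table).
Per gene the genic regions are `UTR5 = [tss, start_codon)`,
`ORF = [start_codon, stop_codon]` (both anchor bases included) and
`UTR3 = (stop_codon, polya_site]` in transcription orientation. The
boundary convention — 3'-UTR includes the poly(A) base and excludes the stop
codon's third base — is a documented choice (the source annotations do not
state inclusivity); it makes the 3'-UTR length equal the stop-to-poly(A)
distance and the genic regions tile `[tss, polya]` exactly, which is
asserted as a property test.

Between each pair of adjacent genes with "clear ends" (both TSS and poly(A)
known) one intergenic region is emitted, exclusive of both bounding anchor
bases (those belong to the flanking UTRs): `TAN` between tandem
(same-strand) genes, `DIV` between divergent genes (two TSSs face the
region), `CON` between convergent genes (two poly(A) sites face it). Where
the UTRs of adjacent genes overlap, the union of the two overlapping UTRs
is emitted as a single `OUR1`/`OUR2`/`OUR3` region (5'/5', 3'/5', 3'/3')
replacing them; OURs are labeled but not profiled by default. Intergenic
regions containing an excluded feature (pseudogene, tRNA or rRNA gene) are
dropped entirely. Genes without clear ends still contribute their ORF but
are excluded from TSS- and poly(A)-anchored profiles and block intergenic
construction across their span.

`relativeOffset` converts genomic positions to signed anchored offsets —
the anchor base is 0, positive is downstream in the gene's orientation —
and is a bijection per gene and anchor.

For length-resolved 3'-UTR analyses, `lengthGroups` sorts regions by length
into five equal-count groups, discards the shortest and names the remainder
Q1–Q4. Equal-count quintiles (rather than equal-width length bands) are
used because the retained shortest group then starts well above 1 bp,
matching how the Q-group bounds behave on real 3'-UTR length distributions;
`k` is an argument.

# Positional statistics

## Binned profiles

`binIRCenters` counts IR centers per 10-bp bin of anchored offset. Two
span regimes mirror the two panel geometries of the source analysis:

* **variable-span kinds** (UTR5, UTR3): the span is the kind's mean length
  (floored to a bin multiple) and only regions *longer than the mean* are
  retained, so every retained region covers the entire span and each bin
  has a constant sample size;
* **fixed-window kinds** (ORF, TAN, DIV, CON; mean lengths ~1.5 kb, 305,
  420 and 209 bp): all regions are retained and 200-bp windows are anchored
  at the two bounding positions. An intergenic region is profiled once per
  flanking gene whose anchor of the requested kind faces it — both poly(A)
  sites of a convergent pair, both TSSs of a divergent pair, one of each
  for tandem — so an IR center in a short region can legitimately be
  counted once in each window.

## Randomized control genomes

The null model conserves local composition exactly: the genome is
partitioned into coding (merged ORF) and noncoding segments and the bases
of each segment are permuted independently and uniformly at random
(`randomizeGenome`). Segment boundaries, lengths and per-segment base
counts are invariant, hence so are genome and chromosome AT content;
annotations carry over unchanged. One hundred such control genomes (seeds
`seed+1 .. seed+100`) are generated per run and the *same* ensemble is
reused across all bins and panels
(`profilePanelsWithControls` scans each control once), preserving the
inter-bin correlation structure of the ensemble. Whether noncoding sequence
should instead be pooled per chromosome before shuffling is not decidable
from the source description; per-segment shuffling (stronger locality
preservation) is the default and `pool = "noncoding"` provides the pooled
variant.

## The Grubbs call

For each bin the real-genome count is pooled with its 100 control counts
($N = 101$) and $G = |x_{test} - \bar{x}| / s$ is compared against
$G_{crit}(N, \alpha) = \frac{N-1}{\sqrt{N}}
\sqrt{t^2 / (N - 2 + t^2)}$ with $t$ an upper quantile of the
$t$-distribution on $N-2$ df. The tested datum is *designated* — it is
always the real-genome count, not the most extreme of the 101 values — so
the default takes $t$ at $\alpha/2$, which makes the call an exact
size-$\alpha$ two-sided test for a designated datum under normality; the
Monte-Carlo calibration test in the suite confirms the rejection rate at
$\alpha = 0.01$ to within three binomial standard errors. The classical
tabulated Grubbs critical values, which add a Bonferroni factor $1/N$
because they are built for the *maximum* outlier, are available via
`bonferroni = TRUE` (and `twoSided = FALSE` for the one-sided table); with
a designated datum they are conservative by roughly a factor $N$. The
direction of a significant call (enrichment above the pooled mean,
deficiency below) is reported separately from its level. Counts are small
integers; no continuity correction is applied, and no multiple-testing
correction is applied across bins — calls are per-bin at fixed
$\alpha \in \{0.01, 0.001\}$, a deliberate mirror of the original design
and a caveat for interpretation.

# Nucleosome occupancy (nNuOc)

Nucleosome calls (BED intervals; e.g. MNase-seq-derived and
chemical-cleavage-derived maps, consumed as two labeled conditions through
one input path) become binary per-base tracks: a base is occupied iff at
least one call covers it (union semantics, no per-call weighting). For each
IR the 0/1 values at center ± 200 bp are extracted, flipped for genes on
the minus strand so that positive offsets are transcriptionally downstream,
divided by the chromosome's mean occupancy (each chromosome's average is
1.0 by definition), and averaged across IRs per offset. Per-window
normalization before averaging is one of two readings of the source
normalization (the other normalizes the averaged curve); they coincide when
all IRs share a chromosome and differ negligibly otherwise, and the
per-window form keeps the group-decomposition identity — the profile over
all IRs is the n-weighted mean of any partition of them (by type, Q group
or arm length), which the tests assert. IRs within 200 bp of a chromosome
end are dropped (not zero-padded) and counted; chromosomes without calls
are excluded. For 3'-UTR occupancy analyses only convergent genes are used
by default (`convergentOnly`), because the nucleosome-depleted promoter of
the downstream gene of a tandem pair would contaminate the 3' profile.

# The synthetic generator

`generateSyntheticGenome` emulates exactly the features the analysis
relies on, and nothing more:

* background bases i.i.d. at AT fraction 0.62 (no dinucleotide or codon
  structure — sufficient for testing the statistics, not a chromatin or
  evolution model);
* 200 genes on 2 chromosomes, strands i.i.d. (tandem/divergent/convergent
  neighbor mix ≈ 1/2, 1/4, 1/4), regional lengths drawn from truncated
  normals around the genome-wide means (ORF 1536 bp rounded to codons,
  3'-UTR 120 bp, 5'-UTR 70 bp, intergenic 300 bp) — the resulting genome is
  ≈ 0.45 Mb, the size 200 genes actually occupy at those densities;
* planted IRs per gene: type III (arm `(AT)4`, R8S0) at offsets −60..−31
  of the poly(A) site in 70% of genes, type II (A-tract arm, R5S3) at
  −20..−11 in 50%, and type VII (mixed-composition arm, R6S1) at +30..+59
  of the start codon in 50% — the three enrichment populations the analysis
  is designed to detect, at their observed offset windows (windows are
  half-open integer sets so 10-bp bins tile them exactly). Planted arms are
  validated against the classifier at generation time, spacers are
  non-self-pairing (all C) and each plant is flanked by non-pairing guard
  bases, so the planted $(R, S)$ decomposition is the unique maximal
  reading of its interval; a post-generation scan of each plant's
  neighborhood re-draws background on the rare chance collision. Placements
  that would collide with an earlier plant in the same gene are re-drawn
  and otherwise skipped, and only realized plants enter the truth table —
  recovery of the truth table is therefore exact by contract, which the
  round-trip tests assert at 100%;
* nucleosomes of 147 bp at ~165-bp repeat length with jittered linkers;
  calls overlapping a depletion window — by default the type III plant
  window itself, so depletion is *over the 3'-UTR IRs* — are dropped with
  probability 0.9. Two conditions are sampled independently from the one
  depletion layout, emulating two independent maps of the same chromatin.

Chromosome length is derived from the drawn gene and gap lengths, so a
layout can never overflow; there is no fixed-length failure mode. The same
seed yields byte-identical FASTA/TSV/BED output.

What passing on synthetic data does *not* show: real genomes have codon
structure, dinucleotide bias, repeat families and correlated nucleosome
positioning, all absent here. The synthetic tests validate the
*machinery* — detection, classification, anchoring, the null model, the
test statistic, the normalization — under known truth; they do not validate
biological conclusions about any real genome.

# Problem sizes and numerical choices

The test suite runs the scanner–oracle comparison on 1,000 random sequences
(≤ 200 bp), the Grubbs calibration on 10⁴ replicates of 1+100 standard
normals, and the profiling recovery checks on the default 200-gene genome
with the full 100-control design; the acceptance script repeats the same
computations at 400 oracle sequences. These sizes give Monte-Carlo standard
errors comfortably below the asserted tolerances (e.g. ±0.003 around the
0.01 rejection rate) while keeping a full run in minutes on one CPU.

Degenerate inputs are handled explicitly: zero pooled standard deviation in
a Grubbs bin returns "not significant" ($G = 0$); empty IR sets after type
filtering are an error in profiling; spans that are not bin multiples are
widened with a warning; a profile over a chromosome with no nucleosome
calls is undefined and those IRs are skipped with a count. Ties in
containment pruning cannot occur after the equal-interval rule (max arm,
then min spacer) because identical intervals with identical arm and spacer
are one record.

# Known limitations

* Only perfect IRs; no imperfect/degenerate repeats, no free-energy model
  of extrusion, no Z-DNA or G-quadruplex calling.
* Per-bin significance without multiple-testing control, by design parity.
* One poly(A) site per gene; no isoforms, no introns (anchors suffice).
* The seven-type table completions for IV and VI are inferred (above).
* The nNuOc input is pre-called nucleosome intervals; read alignment and
  nucleosome calling are upstream of this package.
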