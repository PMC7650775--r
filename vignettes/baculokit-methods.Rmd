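---
title: "Methods: models, parameters and design choices in baculokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in baculokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baculokit)
```

baculokit implements the standard desk work of characterizing a newly
sequenced granulovirus (*Betabaculovirus*) genome: a circular dsDNA
molecule of roughly 100–180 kb, AT-rich, densely packed with
non-overlapping ORFs on both strands, carrying homologous repeat regions
(hrs) and AT-rich direct repeats (drs) in its intergenic space. This
vignette explains each model, the tunable parameters and their defaults,
the numerical choices, and what the synthetic-data tests do and do not
demonstrate about real genomes.

## Coordinates and circular topology

All internal coordinates are 0-based half-open on the plus strand;
GFF3/GenBank files are written and read in the external 1-based inclusive
convention. A feature running across the origin of a circular genome is a
single logical row whose `end` exceeds the genome length (`wrap = TRUE`);
on export it becomes a `join` of two spans and is reconstructed on
import. This matters because published baculovirus genomes are
conventionally linearized on the granulin ATG — `linearize_on()`
reproduces that rotation (reverse-complementing first for a minus-strand
anchor) — and ORFs or scan windows near the conventional origin must not
be split. `N` bases are accepted on input but excluded from GC content
(numerator and denominator) and never matched by motif patterns:
tolerant parsing, conservative scanning.

## ORF prediction and the minimal-overlap rule

`find_orfs()` enumerates start-to-stop ORFs in all six frames, scanning
the doubled sequence on circular genomes so origin-spanning ORFs are
found. Candidates sharing a stop codon are collapsed to the most
upstream start (the longest candidate), the common convention in viral
annotation. The stop codon is excluded from the codon count and the
translation, so reported lengths read as mature protein lengths. The
floor of 50 codons (`min_codons`) is the usual small-ORF threshold for
baculovirus annotation; the default start codon is ATG only, with
GTG/TTG available by flag because alternative starts are rarely invoked
for these genomes.

Published annotations say "minimal overlap" without quantifying it, as
the gene callers they rely on keep that rule internal. We operationalize
it as greedy selection by descending codon count (ties: smaller start,
then plus strand) with a candidate rejected iff it overlaps an accepted
ORF by more than `max_overlap_bp` (default 30 bp), computed on the
circle across both strands. The parameter is exposed so a deposited
annotation can be matched by tuning. Coding density is the union of CDS
intervals (overlaps counted once) divided by genome length.

## Promoter element screening

The scan window is the 180 nt immediately upstream of the initiation
codon on the coding strand (`window_nt`), wrapping across the origin on
circular genomes; a pure distance window is used rather than truncating
at the upstream gene, since published screens do not state a truncation
rule. Three element classes are matched with IUPAC semantics (overlaps
allowed, `N` never matches):

* **early** — `TATAW` with a `CAKT` initiator beginning 25–35 nt
  downstream. The spacing anchor is not stated in the literature we
  model; we measure TATAW-start to CAKT-start by default, with
  `spacing_anchor = "end"` available.
* **lef-type TATA-like** — `TAATWAA`.
* **late** — `DTAAG`, reported anywhere in the window; the familiar
  "about −60 nt on average" is a summary statistic of real genomes, not
  a filter, so it is reported by `summarize_promoters()` rather than
  enforced. A late element whose match starts within `proximal_nt`
  (default 15) of the start codon sets `proximal_late`.

Positions are reported relative to the `A` of the start codon (position
0; upstream negative), which makes statements like "within 15
nucleotides" directly readable off the output.

## Repeat discovery

**Palindromes.** A DNA palindrome is an even-length span equal to its own
reverse complement. `find_palindromes()` extends arms around every
center and reports the maximal span per center; `min_len` must be even
because perfect biological palindromes are even-length. With
`max_mismatch > 0` the arm is extended greedily while the mismatching
pair budget holds.

**Direct repeats.** `find_tandem_repeats()` compares the sequence with
itself at every candidate lag (unit size 10–200 bp by default), marks
positions where the adjacent-copy identity over one unit is at least
`min_identity` (0.8), merges runs broken by mutation clusters at copy
boundaries (gaps up to one unit), trims flank bases that break the
period (requiring the two outermost bases on each side to be
period-consistent, so one coincidental flank match cannot stall the
trim), and scores calls as `copies x identity x unit_length`.
Overlapping calls keep the higher score, and a kept call whose unit is a
multiple of a smaller-unit call covering at least 90% of the same span
is replaced by that call — otherwise per-copy mutations would always
favour the doubled period, whose adjacent copies share fewer
differences. Detection resolution at array boundaries is a few bases
when flanking sequence happens to continue the period; in AT-rich
genomes the permissive defaults also report short two-copy repeats, as
dedicated repeat finders do at equivalent settings. The scan runs on the
linearized plus strand; arrays crossing the conventional origin are not
chased.

**Homologous repeat regions.** `find_hrs()` is a seed-and-extend
detector: exact 12-mer matches (forward-forward and
forward-reverse-complement) are chained along diagonals and extended
under a +1/−1 match/mismatch score with an X-drop of 10, trimming back
to the best-scoring endpoints. Extension is gap-free: hr units diverge
by substitutions at these evolutionary distances, and a gap-free
extension keeps an exact brute-force oracle tractable; the scoring
scheme retains the documented match/mismatch weights. Matched intervals
are clustered (reciprocal 50% overlap), orientations are propagated from
the pairwise match orientations (the first unit of a cluster is labelled
`+`, so orientation labels are relative — a repeat unit has no absolute
strand), units are co-registered by best small offset and a
majority-vote consensus is trimmed to the majority-support span. A
region requires at least `min_units` (2) units of at least `min_unit`
(40) bp at identity-to-consensus of at least `min_identity` (0.7);
units farther than `region_gap` (2000 bp) apart split into separate
regions, so dispersed two-copy repeats a kilobase apart still form one
region. The palindromic core is the longest perfect palindrome of at
least 8 bp in a gap between opposite-orientation neighbours — the
configuration that can extrude a cruciform. Cruciform reporting is
structural only (core plus arms); folding free energies are
parameter-set artefacts of RNA thermodynamics applied to DNA and are
deliberately not computed. Unit *edges* are a detector-defined quantity:
published alignments present them as given, so the package's tests
assess unit count, orientation pattern and consensus length (within a
few bases) rather than exact edge coordinates.

## Gene-content classification, homologs and parity

Protein alignment uses affine-gap dynamic programming (BLOSUM62, gap
open 10 / extend 1) with identity computed over aligned columns
excluding gaps. Classification assigns each ORF to the best panel gene
meeting 25% identity and 50% coverage of the panel representative —
thresholds chosen as a conventional remote-homology floor, since the
original BLASTp cutoffs behind published gene tables are unstated; both
are exposed as arguments. The bundled panel transcribes the published
granulovirus gene-content table: 38 core, 16 lepidopteran-conserved, 20
other, 5 unique genes. Two quirks of the source table are preserved rather than resolved: the
abstract of the original genome description counts 18
lepidopteran-conserved genes while the table itself lists 16 (the
fixture follows the table), and the iap genes at orf85/orf105 are named
iap-1/iap-2 in the table but iap-6/iap-5 in the accompanying text (both
names are recorded, the text's names in the `alias` column).

Homolog mapping is reciprocal best hit under local alignment, one to
one. The gene parity plot places each homolog pair at its ordinal
positions in the two genomes; since published parity plots carry no
statistic, the package defines collinearity as the longest chain of
pairs monotone in both genomes, maximized over circular rotations of
both gene orders and optional reflection of the second, divided by the
number of pairs. It is 1 for identical order, invariant under rotation
of either genome, and drops by roughly the fraction of genes moved by a
translocation.

Whole-genome alignment identity is out of scope; `kmer_identity()` is a
deliberately coarse surrogate (symmetrized containment of
strand-canonical k-mers, k odd ≥ 11 to avoid self-reverse-complement
k-mers) suitable for ranking relatives, not for reproducing
alignment-derived percentages.

## K2P distances, demarcation and trees

`k2p_distance()` computes the closed form
`d = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]` with transitions A↔G and C↔T,
over sites where both sequences have unambiguous bases (pairwise
deletion; ambiguity codes are excluded like gaps, in the same spirit).
Rates are uniform across sites — no gamma correction. Saturated pairs
(non-positive logarithm arguments) return an `NA` marker rather than an
error so downstream code can flag them; `demarcate()` treats any
undefined distance as inconclusive. The demarcation rule follows the
strict reading "more than 0.05 substitutions/site on every marker gene
means distinct species"; the lower same-species bound that some
formulations of the criterion add is not applied, because the source
workflow does not state one — a distance exactly at 0.05 therefore
counts against distinctness, and mixed marker verdicts are
inconclusive.

`nj_tree()` is a standard neighbor-joining agglomeration, provided as
the desk-scale surrogate for the minimum-evolution and
maximum-likelihood searches used in publication-grade phylogenies (those
need external genome sets and dedicated software; claims about clade
placement are integration-level expectations, not unit-test
guarantees). Negative branch estimates are clamped to zero with the
deficit moved to the sister branch, preserving path lengths. Ties in
the Q matrix break deterministically by index order. Trees are
serialized as Newick with `%.8g` branch lengths. Optional bootstrap
support resamples alignment columns with a mandatory seed and counts
recurrences of each internal bipartition. `concat_alignments()` joins
per-gene alignments in a caller-specified reference gene order and
records per-gene column offsets; under pairwise deletion the block
order cannot change pairwise distances, which the tests assert.

## The synthetic-data generator

`generate_genome()` builds a granulovirus-like genome whose defaults are
the study conditions the package is tested under: 20,000 bp (large
enough to carry every feature class, small enough for 50-replicate
tests), 37.18% GC background, 15 ORFs of 80–300 codons with 70% on the
plus strand, one hr of five 104-bp units (two reverse-oriented) around
the perfect palindromic core `GTAAACGTTTAC` with 5% per-copy
substitution, and one AT×30 direct repeat. Background composition is
sampled exactly (the G+C count is fixed and positions shuffled), so
background GC is within 0.5 of target by construction. ORF interiors
are drawn codon-wise from a stop-free, GC-weighted codon distribution;
each ORF is preceded on its coding strand by an in-frame stop so the
annotated start codon is provably the most-upstream start, making exact
coordinate recovery a fair test. The 80-codon floor keeps implants
longer than the chance ORFs an AT-rich background produces, so the
overlap filter cannot evict an implant. Promoter windows for ORFs with
planned elements are rejection-sampled until they contain no motif of
any class, the planned instances are written in at their sampled
offsets, and the finished window is re-scanned (through the guard stop,
exactly as the scanner will see it) to confirm it reports precisely the
planned motifs. The hr flanks next to the core are resampled so no
flanking base pair extends the palindrome, and a base adjacent to each
dr array is forced off the unit period so arrays do not bleed into
AT-rich background.

`diverge()` applies a per-site independent two-parameter substitution
process parameterized by the Kimura transition-probability formulas, so
the K2P estimator recovers the requested distance in expectation, with
`kappa` the transition:transversion ratio (`alpha / 2 beta`).
`diverge_genome_pair()` additionally reverts substitutions that would
create in-frame stops inside implanted ORFs — a crude stand-in for
purifying selection that keeps translations usable — and can invert or
translocate blocks of consecutive genes, recording the permutation as
homolog ground truth for parity tests.

What the generator does **not** emulate: insertions and deletions,
recombination, rate heterogeneity across sites, codon usage beyond a GC
target, overlapping genes, nested or spliced features, and sequencing
artefacts. Passing the recovery tests therefore shows the detectors are
correct under substitution-style divergence on clean sequence; on real
genomes, indel-containing repeat units and low-complexity regions will
degrade boundary precision first.

## Problem sizes and verification

The test suite verifies each stage against an independent oracle:
six-frame brute-force ORF enumeration on the doubled sequence (50 random
circular genomes up to 5 kb), regex-expansion IUPAC matching and a
brute-force promoter matcher on 500-nt windows, an all-substrings
palindrome check, exhaustive-rotation collinearity, an independent
affine-gap alignment DP on short peptides, the closed-form K2P hand
computation and the reference K2P implementation in `ape`, and
additive-matrix reconstruction plus reference-NJ topology comparison for
trees. Implant recovery runs 50 seeded generator replicates at 9 kb with
the default hr/dr settings; K2P bias is measured at 10,000 sites for
true distances 0.01–0.2; NJ topology recovery uses 100 seeded replicates
of an 8-taxon tree with 2 kb sequences and internal branches of 0.05
substitutions/site — moderate divergence where distance methods should
essentially always succeed. One acceptance block requires the deposited
genome record (GenBank MT844067) and runs only where that record can be
fetched or supplied locally; it validates parsed length, GC, ORF count,
coding density, the promoter configurations of specific ORFs and the hr
between *sod* and *p74* against the published description.
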