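---
title: "Methods: skew, rearrangement and recoding in mitoarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: skew, rearrangement and recoding in mitoarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoarch)
```

`mitoarch` analyses the architecture of animal mitochondrial genomes, with
the chelicerates (and in particular the compact, rearranged genomes of
pseudoscorpions and acariform mites) as its motivating system. It covers
three analyses that are usually run together in comparative mitogenomics:
strand-compositional skew at every useful granularity, gene-order
rearrangement classification against the ancestral chelicerate arrangement,
and the construction of recoded phylogenetic matrices that suppress the
compositional signal the first analysis quantifies. A seeded simulator
generates annotated genomes with known ground truth so that every
statistic in the package can be validated without any external data.

## The data model

A `mito_genome` is one nucleotide sequence plus an ordered feature table
over the canonical 37-gene vocabulary (13 protein-coding genes, 22 tRNAs
distinguished as `trnL1`/`trnL2` and `trnS1`/`trnS2` by anticodon family,
2 rRNAs) plus `CONTROL_REGION`. Coordinates are 1-based inclusive, GenBank
style. Circularity is handled with a single convention used everywhere: a
feature with `end < start` spans the origin, occupying `start..L` then
`1..end`. The deposited orientation is taken to be the major strand — the
strand that, in the ancestral chelicerate arrangement, encodes 9 of the 13
PCGs and 13 of the 22 tRNAs; `read_genbank(reorient_co1_major = TRUE)`
re-orients non-standard deposits so CO1 lies major. Ambiguity characters
are preserved verbatim and tallied separately, never dropped.

## Nucleotide skew

Strand skew is measured by the standard asymmetry statistics

$$\mathrm{AT\ skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{CG\ skew} = \frac{C - G}{C + G},$$

computed from raw counts (`count_nucleotides()` then
`nucleotide_skew()`). Positive values mean an excess of A (or C) on the
examined strand; most arthropod major strands show this CA bias, while
several chelicerate lineages show the reversed GT bias. A component is
*undefined* (`NA`) exactly when its denominator is zero, and ambiguous
characters enter neither numerator nor denominator.

Three conventions matter and are fixed here once:

* **Complementation.** Genes on the minor strand are scored in their own
  reading orientation — equivalently, the complement identity of each
  nucleotide is used. `gene_skew_table()` implements this by extracting
  minor-strand genes reverse-complemented, which is algebraically the same
  as `complement_counts()` on deposited-strand counts (a property-tested
  identity: complementing counts negates both skew components).
* **Pooling.** The "across all PCGs" skew at a codon position is computed
  by summing counts across genes and applying the formula once
  (`pooled_skew(mode = "pooled")`), not by averaging per-gene skews. An
  unweighted per-gene mean (`mode = "mean"`) is provided as a sensitivity
  analysis; the two differ whenever gene lengths or coverage differ.
* **Genome row.** The genome-level row uses the literal deposited
  sequence exactly once, so overlapping genes are never double-counted at
  genome level (each gene still gets its own per-gene rows).

Codon positions are assigned by frame index from the annotated start; a
trailing partial codon (e.g. a stop completed by polyadenylation) is
dropped. Stop codons, when fully present, are included in positional
counts. Internally all values are kept at full precision; the TSV writers
format to 4 decimals (2 decimals is the conventional reporting precision
for these statistics).

Third-position skew is summarized into bias categories with the
conventional non-skew band of ±0.2 (`classify_skew_category()`,
`--skew-threshold` in the CLI): `none` when both components sit inside the
band, `CA` or `GT` when at least one component leaves it on one side, and
`mixed` when the two components leave it in opposite directions. The
`mixed` class is this package's addition: the conventional three-color
scheme (blue CA / red GT / purple none) does not define taxa with
opposite-sign third-position skews, and silently folding them into either
biased class would overstate the evidence. `tree_annotate()` writes these
categories onto a fixed Newick topology as leaf comments; it never
re-estimates the tree.

## Gene-order rearrangement

The reference is the ancestral chelicerate (horseshoe-crab-type)
arrangement, shipped as a versioned TSV and loaded by
`ancestral_chelicerate_order()`. Comparisons are rotation-invariant
(circular orders have no privileged linearization) and score **location**
and **strand** as independent axes, because a gene can move without
flipping and flip without moving; the combined statuses are `ancestral`,
`translocated`, `inverted_in_place` and `translocated_and_inverted`.

Two location criteria are offered because the field's verbal convention
("gene X is in a different location") is local while event reconstruction
is global:

* `neighbor_pair` (default): a gene is ancestral in location iff its
  ordered (upstream, downstream) canonical-name neighbors on the circle of
  shared genes match the reference. Neighbor strand is ignored: location
  and strand stay independent. This emulates per-gene location calls, and
  has the known property that one moved gene also disturbs the pair
  context of its old and new flanking genes.
* `shared_block`: both circles are contracted into maximal shared synteny
  blocks (signed: a run may match the reference forward, or reversed with
  all strands flipped), and the smallest set of blocks whose deletion
  makes the remaining circular block orders identical is reported as
  moved, ties broken by fewest genes moved. Genes inside a block inherit
  its status, so a clean k-gene translocation flags exactly k genes.

A single-gene strand flip leaves every name-neighbor context intact, so
both modes report it as `inverted_in_place` and never as a translocation.
A *multi-gene* in-place inversion necessarily reverses gene order inside
the block; the local criterion therefore sees relocation at the block
edges, while the block criterion recovers it as a pure in-place inversion.
This is a real difference in the two definitions, not a defect, and both
results are available side by side.

The control region and non-canonical features (e.g. repeat regions) are
excluded from the comparison universe by default, since rearrangement
counts in this field are conventionally over the 37 genes; flags include
them. Genes missing from one annotation are reported `absent` and excluded
from neighbor computation rather than treated as breakpoints. An ambiguous
annotation (e.g. a tRNA that could be Gln or Met) can be tolerated with
`relabel = c(trnM = "trnQ")`. The deletion-set search is exact up to
`max_deletion_set` blocks (default 8 — ample for a handful of events) and
falls back to neighbor-pair location calls with a warning beyond it.

## Recoded phylogenetic matrices

Translation uses the invertebrate mitochondrial code (NCBI table 5:
AGA/AGG = Ser, ATA = Met, TGA = Trp), hard-coded and exhaustively tested
against an independent implementation. Codons containing ambiguity
characters (the conventional `N` padding for frame errors) translate to
`X`; interior stops are rendered `*` and *flagged rather than fatal*, so
frame repair can follow. Back-translation (`backtranslate_alignment()`)
expands each amino-acid column of an existing alignment to the taxon's
codon, gap residues to `---`, verifying per-taxon that the CDS re-translates
to the row (with `X`/`*` tolerated positionally); any mismatch is an error
naming taxon and column. Alignment and trimming themselves are external
tools' work: this package consumes already-aligned, already-trimmed input.

Four recodings are provided:

* **RY** (`ry_recode`): purines to `R`, pyrimidines to `Y`, at 3rd or at
  1st+3rd codon positions (the two standard settings); untouched positions
  keep their nucleotides and the matrix is declared `mixed_nt_RY` so
  writers can emit correct symbol sets. Ambiguity codes become `?`.
* **NTE** (`nte_recode`): RY recoding restricted to sites where
  transitions are expected to be synonymous under table 5 — every 3rd
  position, plus 1st positions of codon columns consisting of Leucine
  (TTR/CTN) or Arginine (CGN) codons. The published description of this
  scheme does not enumerate the site set, so this default is an
  interpretation, implemented as a swappable pure predicate of the
  column's codons (`nte_default_predicate`); note that under table 5 the
  Arg first-position transition (CGN to TGN) is not strictly synonymous,
  so a stricter user can drop CGN by supplying a predicate. Second
  positions are never recoded, a tested invariant.
* **Physiochemical** (`physiochemical_recode`): the 20 residues collapse
  into six functional groups — hydrophobic {V,L,I,M}, aromatic {F,Y,W},
  small/neutral {S,T,A,P,G}, acidic/amides {D,E,N,Q}, basic {H,R,K},
  sulfhydryl {C} — written as symbols `h a s d b c`. `X` and `*` become
  `?`; the gap pattern is preserved exactly.
* **Concatenation** (`concatenate_partitions`): per-gene matrices join
  into a supermatrix with a `gene = start-end` partition map; taxa absent
  from a gene are gap-filled (logged), and shuffling input order permutes
  partitions but never per-gene content.

FASTA I/O goes through Biostrings. The relaxed PHYLIP dialect is written
and read directly because standard nucleotide/amino-acid PHYLIP readers
reject the recoded alphabets.

## The simulator and what passing tests mean

`simulate_skewed_sequence()` draws i.i.d. bases from the probabilities
implied by a `composition_spec`:

$$p_A = \theta\frac{1+s_{AT}}{2},\quad p_T = \theta\frac{1-s_{AT}}{2},\quad
  p_C = (1-\theta)\frac{1+s_{CG}}{2},\quad p_G = (1-\theta)\frac{1-s_{CG}}{2},$$

with $\theta$ the AT content — the generative inverse of the skew
formulas, so expected empirical skews equal the spec values. The defaults
($\theta = 0.75$, $s_{AT} = 0.20$, $s_{CG} = 0.25$) are the compositional
regime of AT-rich, CA-biased chelicerate major strands; PCGs get
per-position defaults emulating the typical pattern — CA bias at 1st and
3rd positions, a CT bias (negative AT skew) at 2nd positions, and the
strongest CG skew (0.5) at 3rd positions. `simulate_genome()` lays the
genes of any order contiguously on a circle (total 14,724 nt under the
default length plan, in the observed range for compact chelicerate
genomes), drawing every gene in reading orientation from its class spec so
minor-strand genes match their spec after reverse-complementation, and can
insert a tandem repeat region (default 60 nt × 44 copies ≈ 2.6 kb,
annotated `other`) emulating the large repeat insertions seen in some of
these genomes.

Two deliberate simplifications are documented rather than hidden. First,
the model is i.i.d.: no autocorrelation, codon-usage or site-rate
structure. That is sufficient — and appropriate — for validating counting
and skew machinery, which is composition-only; passing parameter-recovery
tests says nothing about alignment quality or phylogenetic signal in real
data. Second, only the start (ATG) and terminal stop (TAA) codons are
overwritten onto PCGs; interior codons stay pure draws, so AT-rich specs
produce a few percent incidental stop codons. Rejecting them would bias
the very composition the generator guarantees (rejection depresses
second-position A measurably), so they are left in and the translation
layer flags them instead. Consequently simulated PCGs have valid frames
but are not biologically plausible proteins.

`apply_rearrangements()` samples non-overlapping translocation and
inversion blocks with enforced spacing: every backbone segment between
event sites keeps more genes than the largest event block. Under that
spacing the minimum-deletion explanation of the rearranged circle is
unique, which is what makes exact `shared_block` recovery a fair test; a
translocation landing one gene from its origin would be genuinely
ambiguous (moving the intervening gene the other way explains the same
order more parsimoniously), and the simulator refuses to generate such
unidentifiable cases. Inversions reverse block order and flip strands;
translocations keep orientation.

All randomness flows through explicit integer seeds, restored-on-exit so
library calls never disturb the caller's RNG stream.

## Numerical and degenerate-input choices

Undefined skew is `NA`, never NaN, and classification of an undefined
component is an error rather than a silent `none`. The non-skew band is
inclusive (|skew| = 0.2 is `none`). Zero-length selections (no PCG rows,
empty position sets) are errors. PCGs shorter than one codon are skipped
with a warning. Report writers use fixed ordering and fixed float
formatting so repeated runs are byte-identical. Rotation ties in gene
orders are broken by anchoring display at CO1 when present (equality
itself is rotation-invariant).

## Problem sizes used in the checks

The bundled checks run entirely from the simulator at desk scale: 200
seeded sequences of length 10^4 for skew parameter recovery (each trial
must land within 3 binomial standard errors on both components — a
criterion that by construction sits near its 99% threshold), 100 seeded
rearrangement scenarios of up to 3 events on the 37-gene ancestral order
for exact shared-block recovery, and single full synthetic genomes
(~17.4 kb with the repeat region) for the architecture and report checks.
Reproduction of the published pseudoscorpion genome statistics requires
the two deposited GenBank records, which are not redistributed with the
package; `scripts/fetch_genbank.R` fetches them into
`inst/extdata/genbank/`, after which the corresponding checks run on real
data.

## Known limitations

The GenBank reader targets well-formed single-record flat files with
CDS/tRNA/rRNA/D-loop features and common location forms (`join`,
`complement`, origin wraps); it is not a general GenBank parser. The
rearrangement module classifies per-gene status; it does not reconstruct
event histories (tandem-duplication/random-loss scenarios) nor compute
breakpoint or common-interval distances. The NTE site set is an explicit
interpretation (see above). Tree annotation requires exact leaf-label
matches after whitespace normalization. The simulator makes no attempt at
tRNA/rRNA secondary structure or sequence evolution along a tree.
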