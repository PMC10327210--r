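---
title: "Methods: discovering and characterizing intragenic toxin-antitoxin systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and characterizing intragenic toxin-antitoxin systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpntools)
```

# The biological problem

Rpn (recombination-promoting nuclease) proteins are widespread bacterial
proteins of the PD-(D/E)XK nuclease superfamily.  They turn out to be
*genes-within-genes* toxin-antitoxin systems: the full-length protein
(Rpn~L~) is a toxic nuclease, while a second, much smaller protein
(Rpn~S~) is translated separately from an internal translation initiation
site (iTIS) inside the same coding sequence, in the same reading frame,
sharing the parent's stop codon.  Rpn~S~ corresponds to the C-terminal
tail of Rpn~L~, dimerizes, binds Rpn~L~, and neutralizes it; the pair acts
in anti-phage defense.

`rpntools` implements the computational procedures around this biology as
a tested pipeline: iTIS discovery from sequence plus initiation-trapped
ribosome profiling, knockout design, four-amino-acid repeat analysis,
transposition-signature scanning, defense-gene neighborhood enrichment,
and structural/biophysical quantification.  Every stage runs on seeded
synthetic data with known truth, so each claim the package makes is
checkable end to end.

# iTIS discovery

## Candidate enumeration

`findInternalOrfs()` scans a coding sequence for in-frame ATG/GTG/TTG
codons at codon index at least `min_offset_codons` (default 30) that leave
at least `min_len_aa` codons (default 20) before the shared stop.  The
small-protein length is the number of sense codons from the internal start
to the end: Rpn~S~ proteins are C-terminal tails of roughly 50 or more
residues, and the defaults deliberately exclude trivially short products.
Leaderless and non-canonical initiation are out of scope.

## Shine-Dalgarno scoring

Bacterial initiation usually requires a purine-rich Shine-Dalgarno (SD)
motif, consensus `AGGAGG`, a few bases upstream of the start codon.
`scoreRbs()` scores the window upstream of a candidate start by **maximum
contiguous match** to the consensus over every alignment offset, keeping
only matches whose spacer (3' end of the matched run to the first base of
the start codon) lies in 4-13 nt, a common bacterial range.  Ties prefer
the shorter spacer.  We use contiguous matching rather than a free-energy
hybridization model deliberately: no thermodynamic parameters need to be
assumed, the score has an exact brute-force oracle (every substring at
every offset), and the package's tests exploit that.  A match of 4 or more
(`min_rbs = 4`) counts as sequence evidence.

## Initiation-peak calling

Antibiotics such as Onc112 and retapamulin trap initiating ribosomes, so
ribosome profiling in their presence shows sharp coverage peaks at
translation starts, while a matched untreated library shows elongation
coverage along the CDS.  `callInitiationPeaks()` computes, per candidate
position, the maximum trapped coverage within +/-9 nt (about the spread of
an initiation footprint) divided by the local median over +/-100 nt
(floored at 1 to avoid division by zero).  A peak requires this local
enrichment to reach `min_fold_local` (default 5) *and* the
trapped/untreated ratio at the maximum to reach `min_ratio_vs_untreated`
(default 3).  The thresholds are declared defaults, all configurable; we
do not attempt A/P-site offsetting of raw footprints, since tracks arrive
as coverage (bedGraph).

`classifyItis()` combines the two lines of evidence into
`sequence_and_profiling`, `sequence_only`, or `profiling_only`;
candidates with neither are dropped.  Transcription-start-site evidence
(dRNA-seq) is deliberately not an evidence class: no processing rule for
it is defined here, and guessing one would be worse than omitting it.

## Knockout design

To show that a small protein is translated from a predicted iTIS, one
ablates the iTIS with as little disturbance to the parent protein as
possible (the experimental pattern is a handful of point mutations that
silence the internal RBS and start while nearly preserving the parent
sequence).  `designItisKnockout()` searches substitution sets over the
codons overlapping the RBS window and the internal start codon, growing
the set from 1 to `max_codon_changes` (default 4), and accepts the first
size at which some set (a) destroys the start codon and (b) drops the
residual contiguous SD match below 4.  Among valid sets of that size it
minimizes, in order: number of parent amino-acid changes; summed
substitution penalty under BLOSUM62 (diagonal minus off-diagonal, so
conservative replacements are preferred); lexicographic order of the
substitutions.  The ordering makes designs fully deterministic and
reproducible.  Stop codons are never introduced, and a design is rejected
if it creates a new in-frame start with an SD match of 4+ within 5 codons.
An impossible design returns an explicit no-plan result rather than an
error.

# Four-amino-acid repeat variation

Rpn C-terminal domains vary between strains of the same species by tandem
four-residue repeats, typically one hydrophobic residue plus three
charged-or-glycine residues, beginning 8-20 residues after the initiating
Met.  `findTandemRepeats()` reports maximal, non-overlapping exact tandem
arrays of period 4 (an optional per-unit mismatch tolerance exists for
distant homologs but the default is exact, since observed arrays are
near-perfect).  Two normalization rules matter:

* **Phase canonicalization.**  An array `KGIEKGIEKGIE` can equally be
  read as `GIEK...` starting one residue later.  The reported `unit` is
  the lexicographically smallest rotation (here `EKGI`), so homologs
  report comparable units regardless of where their arrays happen to
  start; `unit_as_found` preserves the phase as it occurs.
* **Primitive-period filter.**  A homopolymer run is a period-1 repeat,
  not a period-4 repeat; arrays whose unit has primitive period below 4
  are excluded from period-4 output rather than double-reported.

`compareRepeatCounts()` counts copies per homolog, tabulates pairwise
copy differences, and checks *indel consistency*: in pairwise global
alignments (match +1, mismatch -1, gap open -5, gap extend -1, all
configurable), every gap block touching a repeat region must have a
length divisible by 4 -- strains should differ by whole units.  Automated
alignment may phase repeats differently from a manually curated alignment
in edge cases; canonicalization is the declared arbiter.

# Transposition signatures

Because rpn genes are often annotated as "putative transposases", the
package tests for the two signatures that autonomous insertion sequences
carry: terminal inverted repeats (ITRs) and flanking target-site
duplications (TSDs).  `scanTerminalInvertedRepeats()` searches the first
and last 50 bp for the best reverse-complement arm pair, mismatch-tolerant
(default 1) because real ITR arms diverge; ties prefer longer arms, fewer
mismatches, then proximity to the element termini, where biological ITRs
sit.  `scanTargetSiteDuplication()` requires an *exact* direct repeat
immediately flanking the element, because a TSD arises from replication of
one site and is expected identical; the reported length is capped at the
top of the search range.  `detectTandemDuplications()` finds adjacent
direct-repeat blocks (gap at most 10% of block length) by exact 16-mer
seeding and ungapped extension -- the structure expected when gene arrays
grow by tandem duplication rather than transposition.
`transposaseVerdict()` is true only when an ITR or TSD is present; rpn
elements are expected to report neither.

# Defense-gene neighborhood enrichment

Anti-phage defense systems cluster in genomic "defense islands".  The
package quantifies this as a per-gene observation: the fraction of
defense-flagged genes among up to 10 genes on each side of a focal gene
(window in gene count, not kb; both the window and the flag catalog are
inputs, not assumptions).  Focal fractions are compared with fractions
around randomly sampled genes -- by default excluding focal genes and
their window neighbors from the pool, so the null is not contaminated --
using a Mann-Whitney U test written from scratch:

* `U = #\{(i,j): x_i > y_j\} + 0.5 #\{ties\}`.
* For tie-free samples with both sizes at most 25, the p-value is exact,
  from the full counting recurrence
  `f(n, m, u) = f(n-1, m, u-m) + f(n, m-1, u)`; the test suite checks the
  entire distribution against complete permutation enumeration for all
  sizes up to 8.
* Otherwise a normal approximation with tie correction and continuity
  correction is used; it matches the reference implementation in
  `stats::wilcox.test` to nine decimals.

The primary test is one-sided (greater), the enrichment hypothesis; the
two-sided p-value is reported alongside.  The per-gene-fraction
observation unit was chosen over pooled counts because it matches how the
distributions are displayed and keeps genes exchangeable under the null.

# Structural descriptors

Rpn~S~ folds as a compact three-alpha-helix bundle and dimerizes through
its long first helix.  The package computes three descriptors from a PDB
file:

* **SASA** (`sasa()`): Shrake-Rupley sphere sampling with a deterministic
  Fibonacci point lattice, 960 points per atom by default (floor 92),
  probe 1.4 Angstrom, radii C 1.70, N 1.55, O 1.52, S 1.80 Angstrom.  An
  isolated carbon has the closed-form area 4*pi*(1.70+1.40)^2 = 120.76
  Angstrom^2, which the implementation reproduces within 1%; two
  overlapping spheres have a spherical-cap closed form, reproduced within
  2%.
* **Buried interface area** (`buriedInterfaceArea()`):
  SASA(A) + SASA(B) - SASA(AB), the two-sided ("total") convention, which
  is the common reading of a "total buried surface area"; a `per_side`
  flag halves it for the per-monomer convention, since printed values in
  the literature are sometimes one and sometimes the other.
* **Helix segments** (`assignHelices()`): residue windows with
  d(CA_i, CA_i+3) in [4.8, 5.8] and d(CA_i, CA_i+4) in [5.9, 6.9]
  Angstrom are helical; runs are merged across single-residue gaps and
  reported if at least 4 residues long.  The C-alpha-geometry criterion
  needs no hydrogens and is sufficient for counting helices in a bundle;
  it is not a DSSP replacement.

The toy-structure generator builds single canonical helices (radius 2.3
Angstrom, rise 1.5 Angstrom/residue, 100 degrees/residue -- the geometry
of backbone dihedrals phi = -57, psi = -47), extended strands, separated
chains, and a synthetic two-chain three-helix-bundle dimer whose long
first helices pack against each other.  The synthetic dimer is a stand-in
used to exercise the descriptor pipeline; it is not the experimental
crystal structure, and quantitative interface areas from it characterize
the toy geometry only.

# Biophysical and phage-assay arithmetic

`inferStoichiometry()` fits subunit copy numbers to a SEC-MALS mass over
a constrained grid (single species; equimolar pair; free pair), minimizing
the absolute mass residual with ties broken toward fewer subunits.  The
equimolar constraint exists for a documented reason: fitting 74.1 kDa
with subunits of 33.3 and 5.4 kDa unconstrained prefers 2:1 (72.0 kDa,
residual 2.1) over the symmetric 2:2 complex (77.4 kDa, residual 3.3).
The symmetric call rests on orthogonal evidence (the small protein is a
dimer on its own, and the complex is symmetric in the crystal), so the
constraint is a declared modeling choice, visible in the output next to
the runner-up composition -- not a hidden fudge.

`titer()` averages countable plaque rows (3-300 plaques, the standard
counting window) as count x dilution / volume, with an explicit
below-detection result carrying the limit.  `efficiencyOfPlaquing()` is
the test/control titer ratio, reported as an upper bound when the test
strain is below detection.  `burstSize()` divides the plateau mean of a
one-step growth curve by the infected-center concentration; whether a
free-phage baseline at t = 0 is subtracted is exposed as an optional
parameter rather than assumed.

# The synthetic-data generators

Each generator is a pure function of its arguments and seed, and returns
(or embeds) the ground truth needed to predict downstream results without
re-deriving them from the data.

* `simulateRpnLocus()` emits one contig with a 120-codon parent CDS, an
  internal in-frame start (default codon 70, leaving a 50-residue small
  protein, mid-range for Rpn~S~), and a planted SD hexamer with
  configurable contiguous match (default 6) and spacer (default 7 nt).
  Construction is made exact by a deterministic repair pass: internal
  stops, competing in-frame starts within 5 codons of the iTIS, and
  accidental SD matches stronger than the configured one are each
  destroyed by writing a cytosine, which can never form part of a start
  codon, a stop codon, or the purine SD consensus.  The planted score is
  therefore exactly what `scoreRbs` reports, and the planted start is the
  only one its initiation peak can be attributed to.
* `simulateRiboseqTracks()` draws per-base Poisson counts at
  `background_depth` (default 2) over each CDS for both libraries -- the
  simplest model for count data -- and adds 5-nt plateaus of height
  (enrichment - 1) x background at every annotated start and every truth
  iTIS in the trapped library (default enrichment 50; recovery tests use
  10, the harder condition).  Real ribosome dwell-time structure, codon
  bias, and library-size effects are deliberately not modeled, so passing
  recovery tests demonstrates correctness of the calling logic under
  Poisson noise, not performance on real libraries.
* `simulateStrainPanel()` inserts 0..k copies of a four-residue unit
  (default KGIE) 12 residues after Met -- the middle of the observed 8-20
  range -- into a shared base protein sampled from residues absent from
  the unit, so the array boundary is unambiguous and the truth copy
  number exact.
* `simulateDefenseContext()` lays out 4000 genes (a typical bacterial
  genome scale) with 50 evenly spaced focal genes, flags genes within 10
  genes of a focal gene with probability `p_near` and all others with
  `p_bg`.  The genome-scale default matters: focal loci in real genomes
  are sparse (a handful of rpn loci among thousands of genes), and a
  dense design where focal windows tile the genome makes focal and random
  neighborhoods draw from the same pool -- the degenerate case in which
  no test can or should find enrichment.

# Validation problem sizes

The shipped test suite validates: RBS scoring against exhaustive
enumeration on 300 random windows; ORF scanning against brute force on 50
random CDSs; iTIS recovery on 200 seeded loci at 10x peak enrichment
(sensitivity at least 0.95, no false both-evidence calls); knockout
designs re-verified by re-scanning on 100 loci; the exact U distribution
against complete permutation enumeration for all sample sizes up to 8;
type-I calibration over 1000 seeded null runs (rejection at alpha = 0.05
within [0.03, 0.07]) and power over 100 effect runs (p < 0.01 in at least
90%); the repeat caller against exhaustive array enumeration on 1000
random strings; ITR/TSD recovery on 100 planted elements with shuffled
controls checked against quadratic-scan oracles; and the SASA closed
forms above.  These sizes keep the default suite in the minutes range
while leaving each estimate's Monte-Carlo error well inside the asserted
margins.

# Known limitations

* SD scoring is contiguous-match only; initiation strength is not a
  thermodynamic prediction.
* Peak calling assumes coverage tracks are already mapped and offset;
  no BAM/footprint processing is included.
* Repeat detection is protein-level and exact by default; profile/HMM
  repeat detection is out of scope.
* The helix assignment counts helices; it does not classify other
  secondary structure.
* The synthetic dimer exercises the structure pipeline but is not the
  experimental crystal structure; buried-area magnitudes from it are
  properties of the toy geometry.
* Cross-strain element-boundary comparison (multi-genome synteny) is out
  of scope; the mobility module scans single elements.
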