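---
title: "Discovering, classifying and dating centromeric LTR retrotransposons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering, classifying and dating centromeric LTR retrotransposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`crckit` implements a complete desk-scale pipeline for the annotation of
centromeric LTR retrotransposons in genome assemblies: de novo structural
discovery of candidate elements, translated-search domain annotation,
chromodomain / CR-motif typing, family definition from a bootstrapped
reverse-transcriptase (RT) phylogeny, non-autonomous element classification,
a genome-wide copy census, Kimura two-parameter (K2P) insertion dating,
repeat-density tracks, satellite-array detection and region composition
reports. Because chromosome-scale assemblies of centromeric regions are
rarely redistributable, the package ships a first-class synthetic-genome
module that plants elements of known family, age, completeness and nesting;
all validation is phrased as recovery of that planted truth.

An LTR retrotransposon is modelled as two near-identical long terminal
repeats (LTRs, 5'-TG ... CA-3') flanking an internal region that carries, in
*Gypsy* order, the GAG, PR, RT, RH and INT coding domains, a primer binding
site (PBS) just downstream of the 5' LTR, and a polypurine tract (PPT) just
upstream of the 3' LTR. Centromeric (chromovirus-type) families carry either
a chromodomain downstream of the integrase or a CR targeting motif adjacent
to the 3' LTR. At insertion the element is flanked by a short (4-6 bp)
target-site duplication (TSD) and its two LTRs are identical; both decay
with time, which is what detection tolerances and dating exploit.

# The synthetic generator

The generator is the package's definition of the study conditions, not a
tuning dial.

* **Background** is i.i.d. nucleotide sampling at a target GC content
  (default 0.38, a plant-like euchromatic value). There is no isochore or
  k-mer structure: the background is the null model for detector
  specificity. Users can substitute real flanking sequence by planting into
  their own FASTA.
* **Substitution process**: each site receives a Poisson number of K2P
  substitution events with mean `age x rate`; each event is a transition
  with probability `kappa/(kappa+2)`. The default rate is 1.3e-8
  substitutions per site per year and `kappa = 2`; dating is consistent
  under any `kappa`, which the tests exploit. Multiple hits are modelled, so
  K2P correction of the output is unbiased. Indels are *not* simulated
  inside elements — dating operates on substitution divergence only, and
  large deletions are modelled by the explicit truncation decay classes.
* **Templates**: ten family templates (A-H, X, Y) are built from bundled
  synthetic protein exemplars (reverse-translated with a fixed codon table),
  with 700-bp LTRs and total lengths of roughly 6.0-7.8 kb, matching the
  reported size range of centromeric *Gypsy* families (5,971-8,088 bp
  elements, 661-781 bp LTRs). Family A carries a chromodomain; all others a
  CR motif. Family founders diverge from a common ancestor by 0.32 expected
  substitutions per site, which places between-family RT identity near
  55-60% (the "distant" band) while within-family identity stays near 90%.
  Targeting motifs, PBS and PPT are kept conserved across founders, and
  in-frame stop codons introduced by founder divergence are recoded —
  emulating purifying selection on active lineages. Coding domains decayed
  by *age* mutations may acquire stops, as in real degenerating copies.
* **Decay classes**: `complete` (TSD, both LTRs), one-sided truncations
  (keep 60% from the intact end), `internal_deleted` (both LTRs, 10% of
  each internal end retained) and `fragment` (a central slice of the stated
  fraction, no LTRs, no TSD). Nested insertions land at the midpoint of the
  host's realised interval and enlarge it.
* The default TSD length is 5 bp (configurable 4-6), the common range for
  LTR retroelements.
* The satellite monomer used in array tests is an arbitrary 170-bp synthetic
  stand-in (a typical plant centromeric monomer length); no real monomer is
  implied, since the motivating system has none.

What passing tests on this generator do **not** show: robustness to indels
within LTRs, to assembly artefacts, to soft-masked or gapped input, or to
deeply nested insertion stacks older than the detector's identity floor.

# Structural detection

Detection is a seed-chain-extend direct-repeat search. Exact 20-mers
occurring twice on the same strand at a spacing compatible with the element
length range are chained on a shared diagonal (band 30 bp; without indels a
true LTR pair has constant spacing). Chains of at least 3 seeds are extended
by local alignment (match 2, mismatch -3, gap open 5, extend 2) of the two
padded windows into a maximal similar repeat. Candidates must satisfy the
LTR length range (100-2,500 bp), the element length range (1,000-18,000 bp)
and the LTR-pair identity floor (80%). These default ranges bracket the
observed family dimensions with headroom; the stricter 99% pair-identity
cutoff used to pick elements for careful annotation is a downstream filter,
never a detection filter. Overlapping candidates are resolved by keeping the
highest `identity x min(LTR length)` — a deterministic rule favouring
intact elements.

Boundary refinement searches jointly for TG/CA termini: because the LTRs
are copies of one sequence, the true element start shows TG at the 5' LTR
start *and* at the corresponding (diagonal-offset) 3' LTR position; ends
likewise show CA twice. Candidate placements within +/- 20 bp are scored by
these four motif matches plus a strong bonus for an exact flanking 4-6 bp
TSD, with a tiny penalty on the shift so that ties resolve toward the
alignment. An absent TSD is recorded, not fatal. Nested elements are
recovered by a second pass with first-pass elements masked.

The PBS is the best match (>= 11 bp, at most one mismatch) of the reverse
complement of a bundled tRNA 3'-end set within 20 bp downstream of the 5'
LTR; the PPT is a >= 10 bp window of >= 80% purines within 30 bp upstream of
the 3' LTR. Minus-strand elements are analysed in element orientation and
mapped back.

# Domain annotation

All six reading frames are translated and locally aligned (BLOSUM62, gap
open 10, extend 0.5) against a bundled exemplar set of GAG, PR, RT, RH, INT
and chromodomain proteins. The bundled set is *synthetic* — one or two
exemplars per domain generated for round-trip testing — and is a documented,
swappable fixture (`domain_config(reference_set = ...)`): real annotation
requires a real reference set, which is not redistributable in bulk. Hits
must reach 40% protein identity, 50 aligned residues and a BLOSUM62 score of
100; the score floor matters because short chance local alignments can reach
40-50% identity while never reaching a high score. Hits to the same domain
separated by at most two codons are joined (frameshift/stop repair), and a
masked re-scan recovers secondary copies (e.g. from nested insertions). The
RT domain enters the phylogeny only when at least 150 residues long
(longest wins; ties by identity, then leftmost).

The CR motif is modelled as a nucleotide profile near the 3' LTR (window
1,000 bp, 65% identity over >= 40 bp) rather than a protein domain, because
it is a terminal targeting motif without a published consensus for this
system; the bundled profile is synthetic and meaningful only for round-trip
tests. When both a chromodomain and a CR hit occur, the chromodomain wins as
the more specific protein evidence.

# Classification

Superfamily follows coding-domain order: integrase downstream of RNase H is
*Gypsy*, upstream of RT is *Copia*; coding hits in ambiguous order are
`unclassified_autonomous`; no POL hits at all means `non_autonomous`.

Families are defined on the RT phylogeny. Pairwise RT identity uses global
alignment with gap columns counted as mismatching columns (a stretcher-like
convention the identity matrix depends on; note the LTR-pair identity used
in detection *excludes* gap columns — both conventions are deliberate and
documented). The tree is neighbor joining (Saitou-Nei Q criterion) written
in the package; negative branch lengths are clamped to zero with the deficit
moved to the sister branch, and Q ties break by the lexicographically
smallest label pair, making the topology independent of input order. The
multiple alignment for bootstrapping is delegated to MAFFT (a standard
aligner available on the PATH); columns are resampled per replicate,
distances recomputed with the gaps-as-mismatch convention, and support is
the percent of replicates containing each bipartition. Groups are maximal
supported clades (default support >= 70%) whose members all share >= 80%
pairwise RT identity; singletons are allowed, every RT belongs to exactly
one group, and the representative is the member with the highest mean
identity to its group. The support and identity thresholds are package
defaults chosen to give a clean partition on the synthetic mimic of the
three-genome, ten-family design; both are configuration, since no canonical
values exist. Whether a published between-group identity table derives from
representative-vs-representative or mean all-vs-all comparisons is generally
ambiguous; `group_identity_matrix()` reports representatives and exposes
all-vs-all as an attribute.

Non-autonomous elements follow a decision table: GAG without any POL domain
is TR-GAG; no coding hits and total length <= 1,500 bp with each LTR <= 250
bp is TRIM; no coding hits and length >= 4,000 bp is LARD; anything else is
unclassified, and autonomous input is a wiring error. The length bounds
follow the conventional TRIM/LARD definitions and are configuration.

# Census, dating, density and satellites

The census seeds 12-mer matches of a family representative on both genome
strands, merges same-strand seed clusters separated by at most 50 bp, and
scores each merged region by local alignment. Coverage is the aligned
fraction of the representative; identity counts gap columns (masking-tool
convention). Copy classes are strict: complete requires coverage *and*
identity above 0.80; fragments require identity above 0.80 and coverage in
(0.10, 0.80]. The classes are disjoint — a hit is a fragment only when it is
not complete — which matches censuses that tabulate the two classes in
separate columns. A 0.20 divergence cap (the `-div 20` masking convention)
applies to the census-hit density track.

Insertion dating re-aligns the two LTRs of each detected element locally
(with a few bp of context, so detection boundary slop cannot inflate the
estimate), counts transitions P and transversions Q over ungapped columns,
and computes `K = -1/2 ln((1-2P-Q) sqrt(1-2Q))`, flagged (not clipped) when
the log argument is non-positive. Time is `T = K / (2r)` with `r = 1.3e-8`
per site per year by default.

A fundamental precision limit is worth stating: with ~700-bp LTRs, the
expected number of substitution events separating a pair at age `T` is
`lambda = 2 T r L` — about 9 at 0.5 Mya. The realised count is Poisson, so
even a perfect estimator has a per-element median relative error of roughly
`0.675 / sqrt(lambda)` (~22% at 0.5 Mya, ~16% at 1 Mya, ~9% at 3 Mya)
against the planted age. Dating of *young* elements is therefore reliable in
aggregate (the median *estimate* across many copies is nearly unbiased) but
not per element, and the package reports per-age medians so this floor is
visible rather than hidden.

Density tracks report the covered fraction (annotations flattened first) or
midpoint counts per sliding window; the defaults are 500/100 kb for
pseudochromosome plots and 100/20 kb for the 2-Mb synthetic chromosomes.
Tandem arrays are detected by k-mer recurrence periodicity: positions whose
12-mer recurs at a spacing within the monomer range are clustered, a
dominant period must explain at least `min_copies` repeats with dense
support (>= 25% of positions) and adjacent monomers must align at >= 80%
identity. Element LTm pairs never masquerade as arrays because their spacing
exceeds the monomer range and their support density is low. Age histograms
call peaks as bins exceeding both neighbours and at least twice the median
bin count, with a floor of two counts (peak descriptions in the motivating
literature are qualitative; referencing the median over *all* bins rather
than non-zero bins matters because with tightly clustered ages most
non-zero bins are themselves peak bins).

# Numerical and design choices

* All internal coordinates are 0-based half-open; writers alone convert
  (GFF3 1-based inclusive, BED/bedGraph 0-based half-open).
* All randomness flows from one master seed through
  `derive_seed(seed, tag)`, so adding a stage never perturbs another
  stage's stream, and identical configuration plus seed gives byte-identical
  non-log outputs.
* Alignment scoring: nucleotide match 2 / mismatch -3 / gap 5+2 per column;
  with equal-length substitution-diverged inputs the optimal global
  alignment is gapless, which the K2P closed-form agreement check relies on.
* Degenerate inputs: empty sequences, saturated K2P logs, windows larger
  than the genome, and autonomous elements passed to the non-autonomous
  classifier all fail loudly or are flagged; none are silently clipped.
* Problem sizes used by the validation scripts — a 2-Mb genome with 60
  plantings for detection, 200 elements for dating, 90 RTs for family
  recovery, 100 bootstrap replicates — were chosen as the smallest designs
  that leave comfortable statistical margins for the properties being
  measured.

# Known limitations

* No indel process inside elements; boundary refinement and dating assume
  substitution-only LTR decay.
* The bundled domain exemplars, CR profile and tRNA set are synthetic
  fixtures; real-genome annotation requires swapping in curated references.
* Non-LTR repeat classes (LINEs, DNA transposons) are outside detection
  scope; they enter only as census categories if the user provides
  representatives.
* The structural detector targets desk-scale genomes (tens of Mb); for
  chromosome-scale assemblies the per-window candidate cap and seed size
  are the tuning points.
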