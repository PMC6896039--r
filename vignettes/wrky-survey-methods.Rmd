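---
title: "Methods behind the WRKY family survey pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the WRKY family survey pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrkyfam)
```

`wrkyfam` re-implements the computational stages of a WRKY
transcription-factor family survey — domain detection, group and
subgroup classification, duplication-event calling, conserved-intron
typing, and cold-response expression analysis — around the curated
58-gene *Prunus mume* table that ships with the package. This vignette
records the models, the parameters that matter, and the design choices
made where the procedure was genuinely open, so that every number the
test suite checks can be traced to an explicit decision.

## The domain model

A WRKY domain is modelled as a heptapeptide followed, within a bounded
gap, by a zinc-finger spacing grammar.

**Heptapeptide.** The scan pattern is `WRKYG-X-K` with a single wildcard
slot, not the exact pair {`WRKYGQK`, `WRKYGKK`}: the known natural
variant is a point substitution at the sixth position (Q→K, found in two
IIc members of the curated family), so one wildcard position captures it
while still rejecting unrelated strings. Canonicality is recorded as a
flag, never used as a filter. Matches are non-overlapping and reported
left to right.

**Zinc fingers.** Four spacing grammars are recognised, written
`CXnCXmHXH`/`CXnCXmHXC` where `Xk` is exactly k arbitrary residues:

| grammar      | finger type | where it occurs                  |
|--------------|-------------|----------------------------------|
| `CX4CX23HXH` | C2H2        | group I (C-terminal domain), IIc |
| `CX4CX22HXH` | C2H2        | group I (N-terminal domain)      |
| `CX5CX23HXH` | C2H2        | IIa, IIb, IId, IIe               |
| `CX7CX23HXC` | C2HC        | III                              |

`match_zinc_finger()` returns the match with the smallest start index at
or after the search origin; when two grammars match at the same
cysteine the table order above decides, so the most-constrained spacing
consistent with the sequence wins and results are bit-reproducible.

**Pairing.** Each heptapeptide is paired with the nearest downstream
finger whose first cysteine starts within `max_pair_gap = 40` residues
of the heptapeptide end. The full domain then spans at most
7 + 40 + 33 ≈ 80 residues, consistent with the ~60-residue WRKY domain;
the exact ceiling is not dictated by the domain definition, so it is a
configurable argument rather than a constant. Unpaired heptapeptides
are dropped with a warning. Two-domain proteins are tagged `N`/`C` in
sequence order, single-domain proteins `single`.

## Classification

**The rule.** Two domains → group I; one domain with a C2HC finger →
group III; one domain with a C2H2 finger → group II. Zero or more than
two domains raise errors (the latter flagged for manual review rather
than silently truncated).

**Distances.** Subgroups within group II are phylogenetic, not
structural. Sequences are aligned pairwise (global alignment, match +1,
mismatch 0, gap open −5, gap extension −1) and distances are
p-distances over the gap-free columns. The p-distance was chosen over a
corrected model because it is the common default for
neighbour-joining on closely related protein domains and it admits an
exact independent oracle (column counting) in the tests.

**Neighbour joining.** `build_nj_tree()` is a from-scratch Saitou–Nei
implementation: iteratively join the pair minimising the Q criterion;
branch lengths from the standard two-point formulas with negative
lengths clamped to zero; ties broken by the lowest index pair. The
tests cross-check it against `ape::nj` on random matrices and against
the generating topology on additive matrices — `ape` serves only as an
oracle, never as the implementation. Bootstrap support resamples
alignment columns with replacement and reports the percentage of
replicates containing each internal bipartition of the full-data tree.

**Subgroup transfer.** A query inherits the label of the references in
the smallest edge-bounded clade of the unrooted tree containing the
query and at least one reference, provided all references in that clade
agree; on conflict, or when the nearest reference exceeds a patristic
distance of 0.8, the fallback label `IIx` is returned. The ceiling is
the package's own choice: perturbed copies of a reference at ≤15%
substitution sit at patristic distances well below 0.4, while unrelated
proteins aligned under these scores land near 0.9, so 0.8 separates
"placeable" from "unplaceable" with a wide margin. The curated table
itself contains one `IIx` member, a gene whose length and domain
position keep it out of every subgroup clade.

The packaged reference set deserves emphasis: the twelve reference
proteins are *synthetic stand-ins* (generated by `gen_family_proteins()`
with subgroup-appropriate grammars and frozen into
`inst/extdata/atwrky_refs_synthetic.faa`), because the real reference
sequences are external data identified only by accession. Which
accession anchors which subgroup is likewise a best-effort
reconstruction shipped as editable YAML, not code. Subgroup-assignment
results on real data therefore depend on the user supplying real
reference sequences; everything the tests demonstrate is recovery of
planted labels.

**Protein statistics.** Molecular weight is the sum of average residue
masses plus one water, reported in kDa. The isoelectric point bisects
the Henderson–Hasselbalch net charge over the termini and the D, E, C,
Y, H, K, R side chains with the Bjellqvist pKa set (the set behind the
ExPASy Compute pI tool), converged to |charge| < 1e−4 within 200
iterations. Because the curated table's MW/pI were produced from
protein sequences that are not part of the package, per-gene
replication is best-effort; the tests assert the mathematical
properties (additivity of MW, charge root and monotonicity of pI)
rather than table equality.

## Coordinate rules

Coordinates are 1-based inclusive throughout, matching the curated
locus strings; any half-open arithmetic is internal.

**Tandem repeats.** Neighbouring family genes on one chromosome chain
into a tandem event when the inter-gene distance — end of the upstream
gene to start of the downstream gene — is at most 100 kb; maximal
chains of ≥2 genes are events. Both the end→start and start→start
readings of "within 100 kb" reproduce the curated nine-gene answer;
end→start is used because it is the stricter reading of a distance
*between* genes. The survey's original criterion also asks for close
phylogenetic relationship, but the curated table prints one tandem pair
whose members belong to different subgroups (IIc/IIe), so subgroup
agreement is deliberately **not** enforced.

**Clusters.** A gene cluster is a maximal same-chromosome run of ≥3
family genes whose total span (first start to last end) is ≤200 kb.
On the curated table this yields exactly one cluster, the three
group III genes on the first chromosome.

**Percentages.** The duplication summary divides gene counts by the
family size and rounds to one decimal. The "involved in duplication"
figure sums the tandem and segmental counts (9 + 7 = 16 → 27.6% of 58)
rather than taking the set union; both conventions are reported, with
the count-sum primary because it matches how such surveys typically
tally events.

## Collinearity

Segmental duplications are detected MCscan-style. Anchors are protein
pairs with a Smith–Waterman score (BLOSUM62, gap open 11, extend 1)
whose E-value falls below 1e−6. The E-value is a *calibrated proxy*:
Karlin–Altschul with fixed parameters (λ = 0.267, K = 0.041) over a
declared search space (query length × database residues), not an
NCBI-BLAST-compatible statistic — nothing in the package compares raw
E-values across tools. Anchors chain per chromosome pair by dynamic
programming into runs with strictly monotone gene ranks on both axes
(decreasing on one for inverted blocks) and consecutive rank gaps of at
most 25; chains of ≥5 anchors become blocks, and a block is significant
when the product of its anchor E-values is below 1e−10. Gene *rank*
(ordinal position on the chromosome), not base-pair position, drives
the chaining, which removes scale sensitivity. `min_anchors = 5` and
`max_rank_gap = 25` follow common collinearity-tool practice and are
exposed as arguments since only the two E-value thresholds are fixed by
the survey design. Family members participating in anchors inside
significant blocks with family partners are called segmental, grouped
into events by connected components so chained relations (A–B, B–C)
form one triplet event.

## Gene structure and conserved introns

Gene models carry CDS exon intervals in genomic order with a strand
flag; introns are the gaps between consecutive exons, with phase (CDS
bases before the splice, mod 3) and protein context computed in
translation order — reversed for minus-strand models. The
protein→genome projection returns the up-to-two genomic fragments of a
codon, strand-aware.

Two conserved intron positions inside the WRKY domain are typed:

- **R-type** — the splice sits immediately after the *complete* codon
  (phase 0) of an arginine located upstream of the zinc finger's first
  cysteine. Phase-1/2 splits of an arginine codon are classified
  `other`: the conserved position is described as "exactly after" the
  residue, and counting split codons would make the rule ambiguous.
  Any qualifying arginine is accepted (the R of the heptapeptide
  itself qualifies) and the matched residue index is reported, since
  the rule does not pin a unique arginine when several occur upstream
  of the finger.
- **V-type** — the splice sits immediately before the codon of the
  residue six positions after the finger's second cysteine (0-based
  arithmetic: between residues c2+5 and c2+6) and that residue is a
  valine.

Introns inside the domain that satisfy neither rule are `other`; a
domain without any intron is `none`. In the family surveyed, R-type
introns occur in subgroups I, IIc, IId, IIe and III and V-type introns
in IIa and IIb; the generators plant both layouts and the suite checks
exact recovery on both strands.

## Expression and qPCR

RPKM is `count × 1e9 / (length × column total)`. The heatmap transform
is `log10(25 × RPKM + 1)`: the ×25 expansion follows the survey's
display convention, and the unit pseudocount is this package's
interpretation of how undetected genes (RPKM 0) map to the bottom of
the colour scale — it anchors zero at exactly zero and preserves
ranking. A `pseudocount = 0` + floor variant is available for the pure
`log10(25x)` reading. The two-fold candidate filter works on RPKM with
a pseudocount of 1 on both sides of the ratio, since the original
filter's handling of zero denominators is unstated; filtering happens
in RPKM space, not heat-normalised space. Hierarchical clustering uses
Euclidean distance with average linkage cut at k = 6 — the linkage and
metric are the common heatmap defaults, and k mirrors the six
expression clusters the survey reports.

Relative qPCR expression follows the standard 2^−ΔΔCt formulation:
replicate Ct values are averaged *before* differencing, ΔCt is target
minus reference per sample, ΔΔCt subtracts the calibrator sample, and
replicate standard deviations are propagated
(`sqrt(sd_target² + sd_reference²)`) into an RQ range. The calibrator's
RQ is exactly 1 by construction.

## Synthetic data: what it emulates, and what it does not

Each generator is a pure function of spec + seed (byte-identical
reruns, no global RNG leakage) and returns ground truth in the schema
the tests consume.

- `gen_family_proteins()` plants heptapeptide + grammar instances in
  background sequence drawn uniformly over residues *excluding C, H and
  W*, so the planted motifs are provably the only grammar matches; an
  optional perturbation rate mutates positions after planting.
  Real proteomes of course contain C/H/W-rich regions; the exclusion
  makes the planted truth exact rather than probabilistic, which is
  the property the recovery tests need.
- `gen_genome_layout()` places genes with background gaps of 150–500 kb
  (deliberately above the 100-kb rule), plants tandem arrays with
  declared sub-100-kb gaps, copies gene runs to another chromosome with
  per-residue divergence for segmental tests, and realises per-gene
  conserved-intron plans through two-exon models on random strands.
- `gen_expression_data()` draws negative-binomial counts (dispersion
  0.1 per replicate library, three libraries summed per condition — the
  pooled design under which a two-fold filter on single-contrast data
  has useful operating characteristics: ~1–2% false positives and >90%
  per-gene power at a three-fold planted effect).
- `gen_ct_data()` emulates the qPCR design: a reference gene at
  constant Ct, the first sample as calibrator, three technical
  replicates with Gaussian cycle noise (default sd 0.2), and target Ct
  shifted by −log2(RQ).

Because the original study's external inputs (the *P. mume* genome and
proteome, the two RNA-seq archives, wet-lab Ct tables) are not part of
the package, the corresponding results — identifying the 58 genes from
a genome, the identity of the seven segmental genes, the exact 6-up /
11-down freeze candidate lists, the ~25-fold qPCR induction of one
gene — are *not* reproduced from scratch. What the suite demonstrates
instead is that every rule reproduces the curated table exactly where
the table suffices (member counts, group counts, chromosome counts,
tandem arrays, the single cluster, the duplication percentages) and
recovers planted ground truth at scale everywhere else (1,000-protein
domain recovery, 500-query subgroup recovery ≥95%, 500-layout tandem
recovery with zero false events, 200-genome segmental pair recovery
≥95% with ≤1% false pairs, 300-model intron typing, 1,000-trial qPCR
recovery within half a cycle of log2 RQ). Those problem sizes are the
package's standing test conditions and are fixed in the suite.

## Numerical and degenerate-input choices

- NJ tie-breaks take the lowest index pair; negative branch lengths
  clamp to 0; an all-zero distance matrix yields a valid tree with
  zero-length edges.
- p-distance on a pair with no gap-free columns is an error, not NA —
  silent NA would poison a distance matrix.
- Bisection for pI runs on [0, 14] to |charge| < 1e−4, erroring after
  200 iterations rather than returning an unconverged value.
- Block E-value products are capped at the smallest positive double to
  avoid underflow to zero (which would defeat the significance
  threshold comparison).
- A single-exon model yields zero introns (flagged downstream: every
  gene in the curated family has at least one intron).
- `duplication_summary()` warns, but does not fail, when the tandem +
  segmental counts exceed the family size — the count-sum convention
  permits a gene to appear in both lists.

## Known limitations

- Profile-HMM scoring, de-novo motif discovery, structural screening
  and subcellular-localisation prediction are out of scope; domain
  detection is purely grammar-based and will miss degenerate fingers
  whose spacing departs from the four grammars.
- The packaged reference FASTA is synthetic; subgroup assignment on
  real families requires real reference sequences via the same API.
- The E-value proxy is calibrated for ranking and thresholding within
  this package, not for cross-tool comparison.
- MW/pI match the curated table only as closely as the underlying
  sequences, which the package does not ship.
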