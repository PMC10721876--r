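---
title: "Threading peptide pairs onto cross-beta templates: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threading peptide pairs onto cross-beta templates: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilthread)
```

## The model

`fibrilthread` treats cross-seeding prediction as a template-based
stability question: if two peptides can co-assemble into a mixed amyloid
fibril, then a structural model of that fibril, built by threading the two
sequences onto a known cross-beta scaffold, should be energetically
favorable compared with a model built from a non-interacting pair. The
pipeline therefore has three parts — a threading engine, an energy model,
and a threshold classifier — plus a fragment scanner that applies the
three to all fragment pairs of two longer proteins.

### Threading

The template is an ordered stack of at least four identical chains
(layers) of a cross-beta fibril. A query pair `(a, b)` occupies the first
four layers in the alternating pattern A,B,A,B: two chains of each
peptide, with every a-chain adjacent to a b-chain. Alternation maximizes
the number of A–B interfaces, which is the quantity of interest in
cross-seeding; the stacking order inside a real mixed fibril is unknown,
so this is a modeling convention, stated as such.

Queries need not match the template length. A shorter query is aligned to
the middle of the template sequence: for query length $L_q$ and template
length $L_t \ge L_q$ the first query residue lands at template position
$\lfloor (L_t - L_q)/2 \rfloor + 1$, leaving the odd leftover residue on
the C-terminal side. A longer query overhangs both ends, the overhang
split evenly with the extra residue C-terminal, and each terminus may
overhang by at most 8 residues; overhanging residues continue the terminal
strand direction at 3.8 Å per residue. Together with the template length
regime this bounds threadable queries to 14–45 residues. The centering
convention reflects the beta-arch architecture shared by most amyloid
cores: the informative part of a short amyloid fragment is its middle,
not its termini.

The representation is coarse-grained: one CA per residue (inherited
exactly from the template for covered positions) and one side-chain
centroid (SC) placed along the template CA→CB direction at a
residue-specific distance (1.5–3.4 Å, scaling with side-chain size;
glycine has no SC and is represented by its CA when scoring). No rotamer
sampling or minimization is attempted; the ensemble spread instead comes
from isotropic Gaussian jitter on the SC positions.

### Stochastic ensemble and seeding

For each pair, `n_models` models are built and the one with the lowest raw
energy is kept (ties go to the lowest model index). The jitter generator
for every SC point is seeded from the tuple
`(seed, model_index, chain, residue)` through a 31-bit mix, so

* the same seed reproduces every model bit-for-bit,
* any single model — or single cell of a scan matrix — can be rebuilt in
  isolation without replaying the stream, and
* `sigma = 0` gives a fully deterministic model.

Defaults: `n_models = 10` (the conventional build-10-keep-best ensemble
for threading with a stochastic modeler) and `sigma = 0.3` Å, a
perturbation small relative to the 1 Å potential bins but large enough to
diversify bin assignments near bin edges.

### Energy model and the ndope score

The potential is a pluggable table: residue-pair × distance-bin energies
with half-open bins `[lo, hi)`, a 10 Å cutoff (pairs at or beyond the
cutoff contribute exactly zero) and a minimum within-chain sequence
separation of 2 (bonded and adjacent residues carry no packing signal).
The raw model energy is the sum over all unordered qualifying point pairs.
Because peptide lengths vary, the reported score is length-normalized:

$$\textit{ndope} = \frac{E}{L}, \qquad L = \frac{len_a + len_b}{2},$$

with each peptide counted once (for homoaggregation $L$ is simply the
peptide length). Lower scores mean more stable models.

The packaged default table is a coarse contact potential: contacts among
hydrophobic residues and Q/N are favorable (amyloid cores are
hydrophobic/polar-zipper driven), like-charged contacts are penalized, and
a short-range (< 3 Å) clash penalty applies. It plays the *role* of a
full-atom statistical potential such as DOPE without reproducing its
values; consequently any threshold quoted on a DOPE-derived scale cannot
be reused. The package stores the reference thresholds (−256
cross-interaction, −242 homoaggregation) as metadata but refuses to apply
them unless the user passes `use_reference_thresholds = TRUE`; the
supported route is recalibration on the active potential's scale.

### Classification and evaluation protocol

Orientation is fixed throughout: lower score = positive, and the decision
boundary is inclusive (`score <= threshold` ⇒ 1). Candidate thresholds are
the observed scores plus ±∞ sentinels — the simplest candidate set that
contains an optimal ROC point; the operating threshold is the candidate
closest (Euclidean) to the corner (0, 1), ties broken by lower FPR, then
lower threshold. AUC is computed by rank statistics and equals the
tie-corrected Mann–Whitney pair count, a property the test suite checks
against exhaustive pair enumeration.

Evaluation mirrors the standard protocol for this problem: a stratified
30 % hold-out, 5-fold stratified cross-validation on the training part
with the threshold recalibrated inside each fold, and a metric suite of
accuracy, sensitivity, specificity, F1, MCC and AUC, reported as
`mean [std]` (sample standard deviation) over folds plus a single test
row. Stratification is this package's choice — with a small minority
class, unstratified folds can lose a class entirely. Faster- and
slower-aggregation interactions are both treated as the positive class;
the score distinguishes interacting from non-interacting pairs, not the
direction of the kinetic effect.

Degenerate metric denominators are reported as `NA`, never silently 0;
F1 is additionally `NA` when precision or recall is undefined (no
predicted or no actual positives). The Mann–Whitney comparison uses exact
enumeration when the smaller sample has ≤ 8 observations and no ties, and
the tie- and continuity-corrected normal approximation otherwise.

### Fragment scanning

For region localization, protein A is cut into sliding windows (default
width 20 — the length scale of curli repeat units — and step 1, the finest
scan, configurable) and protein B into windows or explicit repeat units
named R1..Rn whose boundaries the user supplies (the packaged YAML config
carries illustrative boundaries only). Every fragment pair is scored with
its own derived seed; runs of consecutively-started called windows are
merged into maximal position ranges (the union of their spans), which is
this package's merging convention for reporting interacting regions.

## The synthetic-fixture generator

`make_template()` builds an idealized parallel in-register stack: strands
along x with a 3.5 Å CA rise, layers translated 4.8 Å along z (the
cross-beta stacking regime), CB alternating ±y at 1.53 Å, and an optional
three-residue beta-arch turn on a circular arc that preserves CA spacing.
Side chains alternate perpendicular to the sheet plane, and in a fibril
the sheet plane contains the stacking axis — so the ±y alternation is both
the physically sensible choice and the one that makes the model of pair
`(b, a)` an exact mirror image of the model of `(a, b)`, giving exact
chain-swap symmetry of the energy.

`make_potential()` provides three styles: `hydrophobic` (the default
table's construction, with a small seeded jitter breaking degeneracy),
`uniform` (control) and `delta` (a single nonzero entry, for locality
tests). `make_benchmark()` samples positive pairs from a hydrophobic/Q,N
rich residue composition and negative pairs from a charged,
proline/glycine-punctuated "beta-prone but non-amyloid" composition,
lengths uniform on 14–45, and scores every pair through the full pipeline.

What the fixtures emulate is the *structure* of the real task: a labeled
benchmark whose positive class scores lower through the physical pipeline,
a calibration/evaluation loop, and scan geometry. What they do not emulate
is real amyloid sequence statistics, real fibril geometry heterogeneity,
or the class imbalance and Abeta bias of literature-derived interaction
data — so green tests demonstrate the machinery and its invariants, not
real-data accuracy.

## Numerical choices and edge cases

* **Bin edges.** Bins are half-open; a distance exactly at the cutoff
  contributes zero. The binned potential is discontinuous at bin edges, so
  energies are only invariant under rigid motion away from the
  measure-zero set of exactly-on-edge distances; the idealized lattice
  template can place glycine CA pairs exactly on an edge (e.g. two 3.5 Å
  strand steps = 7.0 Å), which real, jittered coordinates essentially
  never do.
* **Determinism.** All shuffles (splits, folds) and all jitter run in
  private seeded RNG streams; the user's session RNG state is never
  consumed. Identical config + seed reproduces every output file
  byte-for-byte; timestamps appear only in log lines on stderr.
* **Tie-breaks.** Ensemble argmin: lowest model index. Threshold
  selection: lower FPR, then lower (more negative) threshold.
* **Atomicity.** Output files are written to a temp file and renamed, so
  failed commands leave no partial outputs.
* **Validation.** The residue alphabet is strictly the canonical 20 —
  wildcards are rejected rather than mapped, because the score is a
  residue-pair potential and silent substitution would corrupt energies.
  Template chains are ordered geometrically (by centroid projection on the
  principal stacking axis), not by file order, because deposition order is
  unreliable.

## Problem sizes

The shipped tests and the acceptance script use an idealized 4 × 37
template, benchmarks of up to 200 pairs per class scored with 3-model
ensembles, and a 121 × 5 scan matrix. The benchmark generator defaults to
`n_models = 3` because the class-separation property it exists to provide
does not change with ensemble depth, while the user-facing scoring path
keeps the conventional `n_models = 10`. Each quantity in
`results/acceptance.json` is recomputed from scratch at run time from the
`--seed` argument.

## Known limitations

* Energies are on the packaged potential's own scale; nothing transfers
  numerically from full-atom statistical potentials, only the protocol.
* Four chains only; no fibril elongation, no polymorph search, no
  off-register or antiparallel packing.
* No side-chain rotamers, no relaxation: a pair scored unfavorably because
  of a steric clash that real side chains would avoid is a false negative
  this representation cannot fix.
* Homoaggregation is modeled with the same four-chain build (a = b), a
  convention rather than a measured choice.
* The scanner reports fragment-level geometry; it does not detect repeat
  units automatically, and merged regions inherit the window width's
  resolution.
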