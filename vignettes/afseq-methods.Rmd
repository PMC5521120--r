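---
title: "afseq: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{afseq: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: what the
descriptors and the classifier compute, which knobs matter, what the
synthetic data can and cannot demonstrate, and where the design was
genuinely open.

## The modelling problem

Enzyme/non-enzyme discrimination from sequence alone, in the regime where
alignment is uninformative (structurally diverse sets whose members mostly
share well under 30% identity). The package's stance is alignment-free:
every sequence is mapped to a numeric descriptor vector whose coordinates
are interpretable physicochemical summaries, and a kernel classifier is
trained on a selected subset of those coordinates.

## Sequence (0D/1D) descriptors

A canonical sequence over the 20 standard residues is encoded by an
amino-acid property index, giving an array $I_1,\dots,I_N$. The
electrotopological-state (ES) vicinity operator then redistributes each
value against all others,

$$ES_i = I_i + \sum_{j \ne i} \frac{I_i - I_j}{(d_{ij}+1)^2},
\qquad d_{ij} = |j - i|,$$

treating the chain as a linear topological graph. Key structural facts,
both enforced by tests:

* the pairwise terms are antisymmetric, so $\sum_i ES_i = \sum_i I_i$
  exactly — ES redistributes information, it does not create it;
* ES is the only step that sees residue order: unmodified (`NO`) columns
  are permutation-invariant by construction, ES columns are not (a single
  transposition of a hydrophobic residue along a charged background is a
  sufficient counter-witness).

Arrays are then split over 30 residue groups and collapsed by 17
aggregation operators; a descriptor is one cell of this
index × vicinity × group × operator grid, named
`<Index>_<Mod>_<Group>_<Aggr>`.

### The bundled index tables

Thirteen of the sixteen tables are transcribed from standard literature
scales, with the accession or citation recorded in each table's `source`
field (e.g. `HP` is Kyte–Doolittle KYTJ820101; `IP` is ZIMJ680104; the
z-scales are Hellberg's principal properties; `pa`/`pb`/`pt` are Levitt's
propensities). `dGsU` is computed, not transcribed: hydropathy times the
residue's total accessible surface area. The remaining three (`dHf`,
`L19`, `Xi`) reference a source we could not obtain; they ship as
clearly-labelled **synthetic stand-in tables** — fixed, documented values in
a plausible range. They make the 16-index surface complete and exercisable,
but no scientific claim rests on their particular values, and spot-value
tests pin only the literature-sourced tables.

### Group memberships and operator set

The nine physicochemical group memberships follow standard partitions
(aliphatic `AHR = {A,V,L,I,M}`, aromatic `ARM = {F,W,Y,H}`, polar
`PLR = {S,T,N,Q,C,Y}`, charged `PCG/NCG/CHG`, turn-promoting
`TRN = {G,P,N,D,S}`, small `SML`, uncharged-polar `UNC`), and are
configurable — they are this package's declared choices, not an attempt to
reproduce any specific historical tool's internal tables. Likewise the 17
operators are this package's concretization of the four stated families
(norms, central tendency, dispersion/distribution, information-theoretic):
`N1 N2 N3 AR GM HM MD MX MN VA SK KU Q1 Q3 RG IQ SE`.

### Numerical conventions (bit-reproducibility)

* `GM`, `HM`, `SE` act on absolute values; a zero entry sends `GM`/`HM` to
  0, the all-zero vector sends `SE` to 0. The empty subarray maps to 0
  under *every* operator. Rationale: the feature map must be total — real
  proteins lack some residue types.
* `SK`/`KU` of a zero-variance vector are 0 (avoids NaN columns); `VA` is
  the population variance.
* Quartiles use the linear-interpolation (inclusive-median, R type-7)
  convention.
* Columns constant across a dataset are dropped at generation time and
  logged; this makes realized column counts dataset-dependent, which is why
  initial family sizes are not combinatorially exact. Prediction paths
  disable the dropping so the column set always matches the trained model.

## Pseudo-fold (2D) descriptors

The Nandy embedding walks the sequence on a square lattice: four disjoint
residue classes map to the four unit steps (aromatic $+x$;
nonpolar/aliphatic $-x$; charged $+y$; polar uncharged $-y$ by default —
the partition is configurable, since any fixed physicochemical
four-partition is admissible). Revisited lattice points merge, so a node
represents a cluster of residues; node weight is the arithmetic mean of the
merged residues' property values (consistent with the edge rule: an edge
weighs the mean of its endpoints). The origin starts residue-less and
weighs 0 unless revisited.

Descriptors are the spectral moments $\mu_k = \mathrm{tr}(M^k)$,
$k = 0 \dots 15$, of the weighted matrix. Both conventions — node weights on
the diagonal, or pure adjacency — are supported; the diagonal is kept by
default. $\mu_k$ equals the $k$-th power sum of the eigenvalues (the test
suite asserts this against an eigendecomposition oracle), $\mu_0$ is the
node count, and odd moments vanish on zero-diagonal bipartite paths. Raw
high-order moments span hundreds of orders of magnitude, so the modelling
path stores $\mathrm{sign}(\mu)\log(1+|\mu|)$ by default; raw values remain
available for verification.

## Feature selection

1. **Information-gain filter.** Continuous columns are discretized into 10
   equal-frequency bins (ties share the bin of their lowest sorted
   position; bin count configurable). The supervised threshold is read as
   *per-feature*: keep features with
   $IG \ge 0.15 \cdot H(X)$ bits. A cumulative-budget reading is also
   defensible; the per-feature reading was chosen because it is
   deterministic, order-free and testable in closed form.
2. **Redundancy reduction.** Single linkage over Spearman correlation at
   $|\rho| \ge 0.95$. The magnitude is used because an anticorrelated
   duplicate carries the same information; signed linkage is available via
   `absolute = FALSE`. The cluster representative is the column nearest the
   cluster centroid *after z-scoring* — without standardization "closest to
   centroid" would be scale-dependent.
3. **Genetic wrapper.** Generational GA over bitmasks: population 20, 20
   generations, crossover 0.6, per-bit mutation 0.033, elitism 1,
   fitness-proportional selection; fitness is the positive-class F1 of the
   PUK-SVM in stratified 5-fold CV on folds drawn once per search. The
   whole search is a pure function of its seed.

**Fallback policy.** When fewer than `min_keep` (default 10) features pass
the IG threshold — which is the expected outcome on uninformative data — the
pipeline keeps a seeded *random* subset of `min_keep` features, with a
warning, and passes it through the remaining stages without running the
genetic wrapper. Both halves of this policy are deliberate leakage
hygiene: ranking sub-threshold features by their (spurious) IG would
quietly re-introduce the selection bias the threshold exists to prevent,
and a supervised wrapper search over features already known to carry no
signal can only maximize noise — each measurably inflates cross-validated
accuracy on label-shuffled data.

## The classifier

Soft-margin SVM on the Pearson VII universal kernel

$$K(x,y) = \Big[1 + \big(2\,\lVert x-y\rVert\,
\sqrt{2^{1/\omega}-1}\,/\,\sigma\big)^2\Big]^{-\omega},$$

with $K(x,x)=1$, strictly decreasing in distance, and positive
semidefinite Gram matrices (asserted numerically across random feature
sets). $\omega$ interpolates the peak shape from Lorentzian
($\omega = 1$) toward Gaussian; $\sigma$ sets the width. The quadratic
program is solved by `kernlab::ksvm` on a precomputed Gram matrix; the
kernel itself, the decision function, calibration and the CV protocol are
implemented in this package.

* **Standardization** defaults on and is fitted from training folds only:
  PUK distances are scale-sensitive, and leaking test-fold statistics into
  the scaler is a classic inflation mechanism (the label-shuffle control in
  the test suite guards exactly this).
* **Calibration** is a logistic regression of the class on the SVM decision
  value, fitted on out-of-fold decisions from an internal 5-fold split.
  Inside cross-validation the calibration step is skipped — accuracy and F1
  are computed from hard class predictions, which calibration cannot
  change.
* **Cross-validation** repeats stratified k-fold `n_runs` times, run $r$
  re-splitting with seed `base_seed + r`; per-run metrics are pooled over
  folds and reported as mean ± sd *across runs* (the run, not the fold, is
  the unit of aggregation).
* **Hyperparameters.** Defaults are $C = 1, \omega = 1, \sigma = 1$; a
  small exhaustive `grid_tune()` maximizes mean CV accuracy with ties
  broken toward the smaller, less flexible model (smaller $C$, then
  smaller $\omega$). Published settings for this problem family
  ($C = 0.5$ for 1D descriptor sets; $C = 8, \omega = 21, \sigma = 7$ for
  composition-only sets; $C = 64$ for pseudo-fold sets) are accepted
  directly via `svm_params()`.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` draws, per sequence, a residue-frequency vector from a
Dirichlet centred on its class's frequencies and then samples residues
i.i.d. Defaults, chosen once as this package's study conditions: 100
sequences per class; lengths uniform on [50, 200] (desk-scale but in the
range of small proteins); uniform base frequencies (a `"proteome"` preset
with Swiss-Prot-like backgrounds is included); a 3× frequency shift on
{G, H, R} in the positive class — glycine, histidine and arginine being the
residues whose enrichment most plausibly tracks enzymatic character
(catalytic-site flexibility and acid/base chemistry); Dirichlet
concentration 100, giving moderate between-sequence compositional noise.
An optional planted k-mer motif adds an order-only signal that 0D features
cannot see but ES-modified 1D features can.

This emulates exactly one discriminative mechanism: compositional (and
optionally motif) enrichment. It does *not* emulate domain architecture,
secondary-structure statistics, length–class correlations, phylogenetic
relatedness, or any 3D property. Consequently, passing pipeline tests shows
that the machinery recovers a planted compositional signal without leakage —
it does not certify real-data accuracy. The published-scale reproduction
(the Dobson & Doig benchmark, 691 enzymes / 487 non-enzymes) requires the
user to supply that external dataset; with the 1D family and
$C = 0.5, \omega = 1, \sigma = 1$ the model is expected to approach ~79%
10-fold CV accuracy there.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full 0D+1D pipeline at
100 sequences per class (≈15,000 generated descriptors, shrinking to
thousands after the IG filter and hundreds after redundancy reduction), a
size chosen so the whole suite exercises every stage end-to-end in minutes
on one CPU while keeping the planted effect comfortably detectable. All
randomness — generator, GA, fold splits — flows from explicit integer seeds;
identical seeds give byte-identical FASTA files, subsets and CV reports on
a given machine.

## Known limitations

* The 3D descriptor family (backbone dihedrals, contact and thermodynamic
  indices) is out of scope: it requires solved structures.
* Four-color-map 2D embeddings are not implemented; only the Cartesian
  (Nandy) walk is.
* The autocorrelation vicinity operator is a deliberate stub
  (`apply_ac()` errors): the global ES operator is the implemented choice
  for whole-protein properties.
* `dHf`, `L19` and `Xi` are synthetic stand-in scales (see above).
* Binary classification only; multi-class enzyme hierarchies (EC levels)
  are out of scope.
* The GA wrapper is a stochastic search: different seeds can return
  different near-optimal subsets of near-equal fitness; only the seeded
  result is reproducible.
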