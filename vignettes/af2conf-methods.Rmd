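---
title: "Confidence-aware analysis of predicted structures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-aware analysis of predicted structures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(af2conf)
```

AlphaFold2-style predictors attach two confidence estimates to every model:
a per-residue pLDDT score (0--100, stored in the B-factor column of the
coordinate file) and an L x L predicted-aligned-error (PAE) matrix giving
the expected positional error of residue *i* when superposing on residue
*j*. `af2conf` turns these estimates into concrete analysis decisions. This
vignette explains each method, its assumptions, the tunable parameters, and
the numerical choices made where the procedure left design freedom.

## Confidence segmentation

`split_high_confidence()` smooths the per-chain pLDDT profile with a
discrete Gaussian filter (sigma = 5 residues, kernel truncated at 4 sigma)
and cuts each chain into maximal runs where the smoothed score is strictly
above 70, dropping runs shorter than 50 residues. The strict inequality is
deliberate: a constant-70 model yields no segments. Two boundary choices are
ours: the filter uses a reflective boundary (edge value repeated into the
pad), because zero-padding would artificially depress terminal scores and
truncate terminal domains; and smoothing is strictly per chain -- windows
never straddle a chain break.

`find_domain_like_regions()` reports contiguous uncovered runs of
domain-like length (100--500 residues) whose *median raw* pLDDT exceeds 70.
Raw rather than smoothed scores are used for the median because the median
of a fragment is already robust to local noise; a `use_smoothed` flag
exposes the alternative.

## Disorder inference

Low-confidence regions of predicted models are enriched for intrinsic
disorder, so pLDDT itself is a disorder predictor. `disorder_score()`
offers four per-residue metrics, all oriented so that higher means more
disordered: `plddt` (1 - pLDDT/100), `rsa` (relative solvent
accessibility), and their 20-residue moving-average variants (`plddt_20`,
`rsa_20`; the centered window shrinks symmetrically at chain ends, and a
nominal window of 20 gives an effective interior width of 21). ROC curves
and AUC (`roc_auc()`) are computed per residue with the rank statistic, so
ties count one half and the AUC is invariant under any monotone transform
of the scores.

Relative SASA divides each residue's absolute solvent-accessible surface
area by its maximum exposure in an extended reference conformation. The
estimator is Shrake--Rupley with 960 deterministic golden-spiral test
points and a 1.4 A probe -- any converged SASA estimator is acceptable
here, and test tolerances reflect that. Two representations are supported:

* **Full-atom models**: per-atom spheres with element van der Waals radii;
  per-residue sums are normalized by the published theoretical Gly-X-Gly
  maximum-exposure values (Tien et al. 2013), the standard realization of
  the extended-pentapeptide reference. Values may slightly exceed 1.
* **Calpha-only models** (including all synthetic models): a coarse
  fallback, flagged via the `coarse` attribute, with one sphere per residue
  whose radius derives from the residue's mean volume. Here the reference
  is the free sphere of the same radius computed by the same estimator.
  A flanked-pentapeptide reference would be geometrically inconsistent in
  this representation: a single-sphere residue loses roughly 40% of its
  surface to covalently adjacent spheres, which grossly overstates backbone
  burial, so normalizing by it would inflate every exposed residue's RSA by
  ~1.6x. The free-sphere reference keeps the scale self-consistent: an
  isolated residue scores exactly 1.

We normalize first and smooth second for `rsa_20`; the reverse order would
mix residues with different normalization constants.

## Shape-mer structural space

To compare structures at scale without alignment, local Calpha
neighborhoods are reduced to discrete "shape-mers". Two fragmentations are
used together: sliding 16-residue k-mers and 10 A radius neighborhoods
around every residue. For each fragment, four rigid-motion-invariant
moments of the centered coordinates are computed: the trace (O3), the sum
of principal 2x2 minors (O4) and the determinant (O5) of the second-moment
tensor, and the squared norm of the third-order moment tensor (F). Each
invariant *m* is binned by `round(resolution * sign(m) * ln(1 + |m|))`
(resolution 4 for k-mers, 6 for radius fragments); the fragment kind plus
the four integers is the shape-mer id. The exact invariant formulas and the
log binning are declared normative for this package and are guarded by
rotation-invariance, monotonicity and brute-force-oracle tests. Radius
fragments are not size-normalized by default -- raw moment sums let larger
neighborhoods carry more weight -- and `normalize_by_count` divides the
moments by the point count for users who want size robustness.

Count vectors (whole protein for experimental structures; accumulated over
the high-confidence splits, never across a split boundary, for predicted
models) are TFIDF-weighted with the smoothed inverse document frequency
`ln((1+n)/(1+df)) + 1`, so a ubiquitous shape-mer keeps a factor of exactly
one. The weighted matrix is factorized by NMF (`nmf_topics()`):
multiplicative updates minimizing the Frobenius norm from a deterministic
SVD-based nonnegative initialization, which makes results reproducible
without a seed and the objective provably non-increasing. The full
structural-space map uses p = 250 topics; desk-scale analyses and all tests
use p <= 10, where planted-topic recovery is verified directly.
`assign_topics_knee()` assigns proteins to a topic by sorting the topic's
weight column and taking everything strictly above the knee -- the point of
maximum perpendicular distance to the chord from first to last weight; flat
profiles (maximum chord distance below 1e-9 of the top weight) assign
nothing. Per-residue topic scores multiply each fragment's topic weight by
an RBF kernel of the residue-to-fragment-center distance (sigma = 5 A, our
default; the choice only sets how far a fragment's influence bleeds along
the chain). Whole-structure retrieval uses cosine similarity of count
vectors, which is scale-invariant and nonnegative.

## Rigid domains from the PAE matrix

`pae_graph()` converts the PAE matrix into a weighted residue graph. The
matrix may be asymmetric; we min-symmetrize (`e = min(PAE_ij, PAE_ji)`) on
the reasoning that a pair is rigidly coupled if either direction is
confidently placed. Edges connect pairs with `e` strictly below 5 A
(default), weighted `1/e` with `e` floored at 0.2 A so perfect pairs get a
finite weight. `cluster_domains()` maximizes modularity by deterministic
greedy agglomeration; when no split improves on the trivial partition
(modularity below 1e-9) the connected components are returned, so a
uniformly confident matrix yields a single domain. Communities under 10
residues are discarded. These defaults are declared package defaults --
the clustering is validated by planted-block recovery (ARI = 1 across
seeds for intra <= 3 A, inter >= 15 A blocks of >= 30 residues), not by
equality with any external tool. `extract_rigid_core()` prepares a
molecular-replacement search model: the largest community, trimmed of
residues with pLDDT <= 50, with every B-factor set to the constant 50.

## Adaptive reference restraints

`make_distance_restraints()` restrains working-model Calpha pairs to their
reference distances (d0 <= 8 A, sequence separation >= 3 to avoid
restraining covalent geometry). The potential is "top-out": with deviation
`x = max(0, |r - target| - tolerance)` and well half-width `c`,

```
E(x) = kappa * (1 - exp(-x^2 / (2 c^2 (1 + fallOff * x / c))))
```

is flat (zero force) inside the tolerance, quadratic just outside it, and
its restoring force peaks near `x ~ c` before tapering toward zero, so a
restraint that clearly disagrees with the data releases the model instead
of fighting it. Only the qualitative semantics of the four parameters are
fixed by the method; this closed form and its coefficients (kappa base 10;
wellHalfWidth, tolerance, fallOff scaling linearly with d0 as 0.1 d0,
0.025 d0 and 2 d0/3 respectively) are this package's declared defaults,
all overridable via `params`, and the tests assert only the qualitative
contract (flat bottom, single interior force maximum, tail force under 20%
of peak at 10 c for fallOff = 1, verified against numerical
differentiation).

Confidence weighting uses the lowest pLDDT `p` of each pair: kappa is
scaled by `clip((p - 50)/50, 0, 1)` and tolerance and fallOff by
`1 + (100 - p)/50`, so uncertain pairs pull more weakly, over a wider flat
bottom, and give up sooner; pairs with `p < 50` are disabled outright.
Torsion restraints (phi, psi, chi1 where side-chain atoms exist) take their
targets from the reference's dihedrals (standard signed-angle convention,
verified against an independent implementation) and are disabled below
pLDDT 50 but carry no graded weighting -- graded torsion weighting is a
known open end of the scheme, and we chose the conservative on/off rule.

## Homo-oligomer state scans

To ask a single-chain predictor for an N-copy assembly, the alignment is
copied N times, each copy padded into its own column block, and a query row
with the sequence repeated in every block is prepended
(`expand_msa_homooligomer()`). A state scan collects per-model pTM scores
for each candidate copy number; `predict_state()` aggregates each state by
the *worst* of its model scores (a state counts only if every parameter
set supports it) and takes the argmax, breaking ties toward the smaller
state on parsimony grounds. `scan_success()` implements the evaluation
rule: a scan succeeds if the peak matches the annotation, or if the state
one past the annotated state scores at least 0.1 lower than the annotated
state. The reference phrasing is ambiguous about whether the drop is
measured from the annotated state's or the peak's score; we read it as the
annotated state's, and the margin is a parameter. For fold-and-dock of
heterodimers, `renumber_heterodimer()` implements the residue-numbering
trick of treating both chains as one chain with a 200-residue numbering
gap.

## Pocket confidence

Detected pockets arrive as point clouds. `pocket_residues()` associates a
residue with a pocket when any atom lies within 4.5 A of any pocket point
(a heavy-atom contact convention; our choice, exposed as a flag), enlarged
to 8 A for Calpha-only models since side chains reach several Angstrom
beyond the backbone. `pocket_confidence()` scores a pocket by the mean
pLDDT of its associated residues; strictly above 90 is "high" quality.
Overlap against known sites is residue-level F-score and MCC with
zero-denominator cases defined as 0. The enzyme-candidate filter keeps
models with mean pLDDT >= 70 (inclusive, unlike the strict segmentation
cutoff -- each rule follows its own source convention) and 100--500
residues, ranking by top pocket score.

## The synthetic-data module

Every stage is testable offline against planted ground truth:

* `synth_model()` builds Calpha traces from ideal helix geometry (1.5 A
  rise, 2.3 A radius, 100 degrees/residue), near-extended strands (3.8 A
  steps, alternating pleat) and self-avoiding random-walk coils (3.8 A
  steps, 2.5 A clash radius, 1,000 retries per step before erroring).
  Consecutive Calpha distances always lie in [3.5, 4.1] A. pLDDT is
  Normal(mean, sd) clipped to [0, 100], i.i.d. by default with an optional
  AR(1) parameter -- smoothing-based operations are only interesting under
  correlated noise. The disorder benchmark condition used in tests and in
  `scripts/acceptance.R` is ordered ~ N(90, 5) against disordered
  ~ N(40, 8) with rho = 0.5 over >= 500 residues.
* `synth_pae()` plants block-structured matrices (within-block
  Normal(intra, sd), between-block Normal(inter, sd), diagonal intra/2).
* `synth_oligomer_scan()` plants a true state with score decay `gap` per
  state and Gaussian noise (defaults gap 0.2, noise 0.05, base 0.85 --
  chosen as a realistic separation between supported and unsupported
  states).
* `synth_msa()` mutates copies of a random query at a per-column rate.
* `synth_binding_site()` grows a site from a random seed residue by 3D
  proximity and returns it as the closure of the planted pocket's points
  under the package's own contact mapping, so the true pocket reproduces
  its site exactly (F = 1) while decoys planted >= 15 A away share no
  residues (F = 0).

What the generators deliberately do not emulate: real side-chain packing,
sequence-structure coupling, the network's correlated pLDDT/PAE errors, or
detector-specific pocket shapes. Passing tests therefore demonstrate the
correctness of the package's algorithms and contracts on known ground
truth, not end-to-end performance on real predicted proteomes.

## Problem sizes and determinism

All generators are pure functions of their specification and seed. The
test suite and the acceptance script run at desk scale by design: disorder
benchmarks on 550-residue models, PAE recovery on 80-residue two-block
matrices over 20 seeds, NMF recovery on 40 x 30 count corpora with 3
planted topics, and 1,000-draw Monte-Carlo scans for the oligomer rule.
These sizes were chosen so each property is measured with comfortable
statistical margin while the whole suite stays fast to iterate on.

## Known limitations

* mmCIF is read but not written; models with residue numbers beyond 9999
  cannot be written to PDB.
* The coarse Calpha SASA is a representation-level approximation, suitable
  for ranking and ROC analysis but not for absolute accessibility values.
* The NMF solver is dense; corpora at the scale of full structure databases
  would need a sparse implementation.
* `resolution` in `cluster_domains()` is fixed at 1 (plain modularity); the
  greedy algorithm does not implement a resolution parameter.
* Torsion restraints cover phi/psi/chi1; higher chi angles are omitted
  because the restraint semantics are identical and the fixtures carry no
  full side chains.
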