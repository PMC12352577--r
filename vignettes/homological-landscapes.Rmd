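---
title: "Methods: homological landscapes of functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homological landscapes of functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homconn)
```

## The model

`homconn` treats a functional connectome as a complete weighted graph: a
symmetric matrix `W` of absolute Pearson correlations with unit diagonal.
Absolute values are taken per subject, during FC estimation, so that all
couplings — and hence the threshold parameter — live in `[0, 1]`; group
averages of such matrices are automatically nonnegative, which is why the
package averages after the per-subject absolute value and never needs a
second rectification.

All topology is computed on the dissimilarity `d_uv = 1 − w_uv`. Sweeping
a threshold `t` from 0 to 1 gives a nested family of graphs (edge iff
`d_uv ≤ t`, ties included), and each graph is completed to its flag
(clique) complex: a simplex for every clique. Equivalently, and this is
how the package implements it, a simplex enters the filtration at the
maximum pairwise dissimilarity of its vertices (the Vietoris–Rips rule);
vertices enter at 0. The two formulations agree because a clique exists
at `t` exactly when its largest edge does.

Two Betti numbers can be attached to each stage and they are *not* the
same thing. The graph-level `b1 = |E| − |V| + b0` counts independent
graph cycles and can only grow as edges accumulate. The complex-level
`b1` counts holes that triangles have not yet filled, so it rises and
then falls back as chords triangulate loops. `graph_betti()` reports the
former; `betti_curve()` on a persistence diagram reports the latter.
`example_connectome()` illustrates the divergence: its complex-level
sequence across the six stages is `b1 = 0, 1, 2, 1, 0, 0`, while the
graph-level count keeps rising once chords appear. Any decreasing
first-Betti sequence over a nested filtration is necessarily the
complex-level one; this distinction drives which function the package
uses where.

### Persistence computation

Diagrams are computed by the standard boundary-matrix reduction over the
two-element field (the conventional coefficient choice, which makes
ranks well-defined integers and orientation irrelevant). Simplices are
ordered by (filtration value, dimension, lexicographic vertex tuple), a
total order in which faces always precede cofaces at tied values; any
valid refinement of the filtration yields the same diagram, which the
oracle tests confirm. The reduction is implemented in C++ (columns as
sorted index vectors, symmetric-difference addition), as is usual for
this workload.

Conventions:

* To resolve `H_p`, simplices up to dimension `p + 1` are enumerated;
  `max_dim = 3` (the default of `build_flag_filtration()`) resolves H2.
  The top enumerated dimension is dropped from the output because its
  deaths are not resolved.
* The single essential H0 class has its death capped at 1.0, the
  endpoint of the filtration domain: since weights are nonnegative, at
  `d = 1` every edge is present and the complex is a cone, so H0 is the
  only dimension with an essential class and the cap makes H0 diagrams
  finite multisets, as the Hausdorff comparison requires.
* Zero-persistence pairs (birth = death) are recorded in the diagrams
  but excluded from distances by default: they sit on the diagonal,
  contribute nothing to the Wasserstein optimum, and would pollute the
  Hausdorff death multiset with spurious values.
* An exact cap guards the combinatorics: with `max_dim = 3` the complex
  has `choose(n, 4)` tetrahedra, so the builder refuses `n > 80` unless
  the cap is raised explicitly. Exact from-scratch computation for
  `n ≤ 50` completes in well under two minutes on one CPU; all tests run
  on this from-scratch path.

An independent oracle, `brute_force_betti()`, recomputes any Betti
number at any threshold from GF(2) ranks of explicitly assembled
boundary matrices (bit-packed Gaussian elimination in pure R, sharing no
code with the C++ reduction). The test suite equates the two on
hundreds of random matrices across all three dimensions.

### Diagram distances

Dimension 0 is special: every component is born at 0, so mass moving in
and out of the diagonal — the scenario Wasserstein matching models — is
not meaningful. H0 diagrams are therefore compared as death-value
multisets under the classical Hausdorff distance. The essential death
(1.0) is included on both sides, where it cancels; as a set distance,
Hausdorff is insensitive to multiplicity, a documented consequence of
the formula rather than a bug.

H1 and H2 use the q-Wasserstein distance over partial pairings: matched
intervals pay the max-norm distance between their endpoints, unmatched
intervals pay their distance to the diagonal `(death − birth)/2`, every
term raised to the q-th power and the optimum taken to the 1/q power.
The exponent is applied symmetrically to all three terms. The default
`q = 2` is configurable (any `q > 1`); 2 is the conventional choice that
balances sensitivity to single large features against accumulation of
small ones. The optimum is found exactly by a linear assignment on the
`(nX + nY)`-square cost matrix in which each interval also has
diagonal-projection slots and diagonal-to-diagonal transitions cost 0;
the solver is an `O(n^3)` Hungarian algorithm with dual potentials,
written for this package because no installed R package provides a
linear-sum-assignment routine. A brute-force enumerator over all partial
pairings (`≤ 8` intervals) validates it in the tests. Essential
intervals are rejected from Wasserstein input by construction — under
the capped filtration H1/H2 have none, and H0 uses Hausdorff.

Between empty diagrams the distance is 0; empty versus non-empty is the
total unmatched cost.

## Landscape levels and their conventions

* **Distance tables** bind H0 to Hausdorff and H1/H2 to Wasserstein by
  default; the binding is overridable for methodological comparison.
* **Profiles** report, per condition, the mean and the *population*
  variance (divide by the count) of its distances to the other
  conditions: the variance describes exactly the listed distances, no
  inferential claim intended.
* **Most distinct pair / consensus voting**: argmax ties are broken by
  the lexicographically smallest label pair, so voting is deterministic.
  Each subject's table contributes exactly one vote; counts always sum
  to the number of subjects.
* Per-subject tables use each subject's own filtration (each FC defines
  its own weight levels); nothing is pooled before the diagram stage.
* **Mesoscopic analyses** run on induced sub-connectomes (principal
  submatrices per functional network), not on masked whole-brain
  matrices, so each network's diagram reflects only its internal
  couplings.
* **Super-graph consolidation** sums cross-network weights,
  `W_ij = Σ_{u∈i, v∈j} w_uv`, and normalizes off-diagonal entries by
  their maximum, so the strongest cross-network coupling is exactly 1.
  The diagonal of the normalized matrix is set to 1 and the denominator
  excludes the diagonal blocks (within-network weights are contracted
  away, not part of the quotient's edges): the normalized super-graph is
  then itself a valid connectome and every homological operation applies
  to it unchanged. Normalized entries are invariant under rescaling all
  cross-network weights. On very small super-graphs H2 is typically
  empty; the pipeline reports empty diagrams as empty and continues.
* **KL divergence** between two networks' task-vs-rest distance
  distributions uses a shared equal-width histogram over the pooled
  range (default 10 bins) with a pseudocount of 1 per bin before
  normalization — a deliberately simple, always-finite estimator whose
  direction is `KL(first ‖ second)`; the pipeline emits both directions.
  A degenerate pooled range returns 0. Top-k rankings normalize the
  selected values by their maximum, so the leading pair has strength 1.

## The synthetic cohort generator

`simulate_cohort()` exists so that every stage of the pipeline can be
exercised, with known ground truth, on data whose statistics are
analytically tractable. Regional signals follow a linear latent-factor
model: region `u` in network `i` is
`x_u(t) = λ_i f_i(t) + g h(t) + ε_u(t)` with unit-variance Gaussian
factors and noise. Same-network pairs then correlate at
`(λ_i² + g²)/(λ_i² + g² + 1)` and cross-network pairs only through the
global factor — closed forms the tests use as oracles. A latent-factor
model was chosen over direct covariance sampling precisely for these
closed forms.

A task perturbation `δ` on a network does two things: it strengthens the
network's shared factor (loading `λ + 0.3 δ`) and it adds a cyclic
coordination component — regions load with equally spaced phases on a
pair of ring factors with amplitude `δ`. The strengthening raises mean
within-network coupling, a merge-height (H0) signature; the ring embeds
the network's regions around a circle in correlation space, a genuine
persistent 1-cycle (H1) signature. A perturbation visible to H0 alone
would make first-homology recovery tests vacuous: a uniform increase in
within-network coupling tightens a featureless blob, and blobs have no
loops, so some cyclic reorganization is required for the planted effect
to exist at all in H1.

The default cohort (20 subjects, 40 regions in five networks of sizes
10/10/8/6/6, 300 timepoints, conditions REST/EMOT/WM/MOT, baseline
`λ = 0.4`, global load 0.15, subject jitter sd 0.05) plants a structured
effect: all three tasks share a common engagement perturbation of the
dorsal-attention network (`δ = 0.7`), and the motor condition
additionally reorganizes the somatomotor network (`δ = 0.9`). The shared
component is essential, not decorative. Diagram distances are
near-additive over independently planted features, so if each task
carried only its own private perturbation, the two most-perturbed tasks
would always be farther from each other than either is from rest, and
no planted design could make (most-perturbed task, REST) the most
distinct pair. With a common task component, rest sits apart from the
task cluster and the motor condition protrudes from that cluster, so
(MOT, REST) dominates every other pair — at the group level and for the
large majority of individual subjects. The effect sizes were fixed once,
at values giving a comfortable margin over the sampling noise of
300-timepoint correlations, and the recovery tests then assert success
in at least 90% of 20 independently seeded replicates.

What the generator does *not* emulate: hemodynamics, autocorrelated
noise, motion artifacts, negative correlation structure (signals are
folded by the absolute value exactly as real FCs are, but no
anticorrelated networks are planted), heavy-tailed weight distributions,
or spatial embedding. Passing recovery tests therefore demonstrates that
the pipeline's machinery — estimation, filtration, reduction, distances,
voting — correctly propagates a known topological signal at realistic
noise levels; it does not certify sensitivity on real fMRI cohorts,
whose effect sizes and confound structure are outside the model.

Determinism: a cohort is a pure function of its spec, including the
mandatory seed (there is deliberately no default seed). The per-subject
loading jitter is drawn once per subject and shared across that
subject's conditions, so condition contrasts within a subject are not
confounded by jitter.

## Numerical choices and degenerate inputs

* Symmetry on input is enforced to `1e-8` and then repaired by averaging
  with the transpose; larger asymmetry, out-of-range weights, non-unit
  diagonals, constant time series and mismatched region orders are each
  distinct, named errors.
* Unique weight levels use exact floating-point equality; users wanting
  coarser level sets should pre-round their weights (the package does
  not round silently).
* An edge with `w_uv` exactly equal to the threshold is included.
* All-zero cross-network blocks consolidate to a zero off-diagonal
  super-graph with a warning rather than a division by zero.
* Diagram CSV round trips are lossless to `1e-12` (values written at
  full precision); intervals with `death < birth` are rejected on read.
* H0 death values are 1-Lipschitz in the edge weights (merge heights are
  min-max functions of edge dissimilarities), which the stability tests
  assert empirically at perturbation radii 0.01 and 0.05.

## Problem sizes in the shipped tests

The suite validates the reduction against the boundary-rank oracle on
100 random matrices with 6–12 regions at every distinct threshold for
H0–H2; the Wasserstein solver against exhaustive enumeration on 200
random diagram pairs (up to 8 intervals); Euler identities on all
threshold graphs of 200 random connectomes; H0 stability on 50 perturbed
matrices; and planted-effect recovery on 20 independently seeded default
cohorts (each 20 subjects × 4 conditions × 40 regions, H1 diagrams from
~10,700-simplex filtrations). These sizes keep the full suite in the
single-digit minutes on one CPU while leaving every code path exercised
at a scale where independent oracles are exact.

## Known limitations

* Exact reduction and exact assignment are quadratic-to-cubic in their
  inputs; whole-brain parcellations in the hundreds of regions with
  `max_dim = 3` are beyond the intended desk scale (the builder's cap
  makes this explicit). An optimized external backend could be plugged
  in ahead of the distance layer, but none is required for the package's
  scope.
* No cohomology, zigzag persistence, H3+, bottleneck (`q = ∞`) distance,
  persistence landscapes/images, or significance testing of distances.
* The KL estimator is a fixed-grid histogram; with very few subjects the
  pseudocount dominates and divergences shrink toward 0. That bias is
  deliberate (finiteness and comparability across pairs) and documented
  here rather than hidden behind an adaptive estimator.
* Negative-weight (signed) connectome analysis beyond the absolute value
  is out of scope.
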