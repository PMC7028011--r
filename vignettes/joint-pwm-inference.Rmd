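---
title: "Joint inference of DNA-binding specificities by structure-guided PWM smoothing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint inference of DNA-binding specificities by structure-guided PWM smoothing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwmsmooth)
```

## The problem

High-throughput protein–DNA interaction assays (bacterial one-hybrid
selections, protein-binding microarrays, and their relatives) yield a
position weight matrix (PWM) — a 4 × k column-stochastic matrix of base
preferences — for each assayed DNA-binding domain (DBD).  These PWMs are
conventionally estimated one protein at a time, although the proteins of a
single DBD family (C2H2 zinc fingers, Homeodomains, ...) bind DNA through a
shared structural scaffold: specific, well-characterized residue positions
contact and specify the bases at particular binding-site positions.  Two
domains that agree at those specificity-determining residues are expected to
bind similarly, and the measurement for one carries information about the
other.  Per-protein estimation throws that information away, which matters
because large assays are noisy and unevenly reliable — some proteins are
measured nearly perfectly while others effectively fail.

`pwmsmooth` revises all PWMs of a dataset *jointly*: each protein's estimate
is pulled toward the estimates of structurally similar proteins, with a
single parameter α ∈ (0, 1] setting the balance between fidelity to the
individual measurement and dataset-wide consistency.

## Data model

Each DBD instance is identified by its **core sequence** *a*: the
concatenation of its base-contacting amino acids (four residues for a single
C2H2-ZF domain, binding a 3-bp site).  Instances identical at the core are
aggregated beforehand — `aggregate_by_core()` merges their PWMs by an
unweighted entrywise mean with column renormalization.  Where raw count
matrices are available, sum the counts and use `normalize_counts()` instead;
the mean-of-frequencies rule is the symmetric default when only PWMs
survive.

The structural prior enters through a **contact-frequency matrix** `M[i, j]`:
the fraction of co-complex structures of the family in which DBD position
*i* contacts a base at binding-site position *j* (a contact being a
non-hydrogen base atom within 3.6 Å).  Instances are uniqueness-weighted by
`compute_contact_frequency()` — each structure is down-weighted by the
multiplicity of its aligned DBD sequence, so that redundant depositions of
the same domain do not inflate frequencies; duplicating every instance
leaves `M` unchanged, which is the property the weighting exists to provide.
A DBD position is called **base-contacting** when `max_j M[i, j] ≥ 0.10`
(inclusive), and the **key position** of *j* is the base-contacting position
maximizing `M[i, j]` (ties, which are measure-zero on real data, break
deterministically toward the lowest index).

## The similarity graphs

For every binding-site position *j* a directed graph G<sub>j</sub> over core
sequences encodes the prior expectation `w_j(a, a′)` that *a* and *a′* share
specificity at *j*:

* cores differing at more than `max_mismatch` base-contacting positions get
  weight 0 everywhere (no prior expectation) — `max_mismatch = 1` for
  C2H2-ZFs, up to 4 for Homeodomains;
* a mismatch at *j*'s key position voids the prior at *j*;
* otherwise the unnormalized weight is `∏_{i ∈ D} (1 − M[i, j])` over the
  differing positions D — for a single mismatch exactly `1 − M[i, j]`:
  differing at a position that rarely contacts *j* barely matters, differing
  at a frequent contacter nearly voids the edge.

The product form of the multi-mismatch rule was a genuinely open design
choice; we use it because it reduces exactly to the single-mismatch rule,
penalizes each additional mismatch monotonically, and stays within [0, 1].
Weights are then normalized per node so each core's outgoing weights sum
to 1 (`build_graphs()`), making every core contribute equally to the
objectives below; the graphs are directed because normalization is per-node.
Cores with no edge at any position can receive no information and are
dropped by `filter_isolated()`, mirroring standard pre-processing of such
datasets.

## Two smoothing formulations

Both operate on one binding-site position at a time (positions are coupled
neither in the objectives nor in the constraints; the four bases couple only
through each core's simplex constraint).

**Constrained quadratic program** (`method = "qp"`).  Minimize over all
revised columns Ŝ:

$$\alpha \sum_b \sum_a (S_a[b] - \hat S_a[b])^2 \;+\;
  (1-\alpha) \sum_b \sum_a \sum_{a'} w_j(a,a')\,(\hat S_a[b] - \hat S_{a'}[b])^2$$

subject to each Ŝ<sub>a</sub> lying on the probability simplex.  The
objective is strictly convex (its Hessian is diagonally dominant with
strictly positive diagonal).  A useful structural fact drives the
implementation: the stationary point of the equality-constrained problem is
`Ŝ[·,b] = α (αI + (1−α)L)^{−1} S[·,b]`, where `L` is the Laplacian of the
symmetrized weight matrix.  `αI + (1−α)L` is an M-matrix whose inverse is
entrywise nonnegative, and its rows, scaled by α, sum to 1 — so the
solution is a row-stochastic averaging of the input columns.  It therefore
lands on the simplex automatically: the box constraints of the program can
never be active, and the exact linear solve *is* the QP solution.
`qp_infer_column()` performs that solve and then verifies feasibility to
`qp_feasibility_tol` (1e-9), clipping only float-level negatives; any larger
violation is an error rather than a repair.  The test suite checks the
solver against an independent projected-gradient minimizer over the simplex
on hundreds of random instances.

**Label-propagation adsorption** (`method = "lpa"`).  The default
`anchored` variant iterates

$$\hat S^{(t)} = \alpha S + (1-\alpha) W \hat S^{(t-1)}, \qquad \hat S^{(0)} = S,$$

the absorbing-random-walk form in which a walk re-enters the node's initial
estimate with probability α per step.  For α > 0 the map is a contraction
(spectral radius of `(1−α)W` at most `1−α`), so it converges geometrically
to the unique fixed point `Ŝ = α(I − (1−α)W)^{−1}S`; when the iteration
stops because the largest entry change falls below `lpa_tol`, the
fixed-point residual is below `(1−α)·lpa_tol`.  A `literal` variant that
blends with the *current* iterate instead of the anchor,
`Ŝ^{(t)} = αŜ^{(t-1)} + (1−α)WŜ^{(t-1)}`, is also provided for
finite-iteration experiments; run to convergence it has no anchor and
drifts to a per-component consensus, which is why it is not the default —
the anchored form is the one consistent with the random-walk semantics and
with "balancing the current estimate against the amount of smoothing".
Both variants coincide at a single iteration, where the update is exactly a
weighted nearest-neighbor blend `αS_a + (1−α)Σ w_j(a,a′) S_{a′}` — useful
as the natural baseline that propagation-to-convergence should beat.

Every revised column is a convex combination of probability vectors in both
methods, so simplex membership is conserved exactly; α = 1 is the exact
identity.  Isolated nodes are returned unchanged by construction.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.4 | fidelity-vs-consistency balance; 1 = no sharing.  0.3–0.7 is the useful range; on our synthetic study gain/loss enrichment peaks around 0.4, and pushing lower rewards consistency too heavily. |
| `max_mismatch` | 1 | mismatch budget for a nonzero prior (1 for C2H2-ZF, 4 for Homeodomain protocols). |
| `contact_threshold` | 0.10 | contact-calling threshold defining base-contacting positions (inclusive). |
| `lpa_tol`, `lpa_max_iter` | 1e-8, 1000 | propagation stopping rule; convergence is geometric, so 1000 iterations is generous for any α ≥ 0.01. |
| agreement `threshold` | 0.5 | two columns agree when their Pearson correlation is ≥ 0.5; exposed because conclusions should be (and in our tests are) robust to it. |

PCC is the agreement measure because it ignores information-content
differences — overall IC differs systematically between assay platforms and
is changed by smoothing itself.  A uniform column has no defined PCC; such
pairs are excluded from agreement fractions and counted separately
(`n_undefined_pcc`), except that two entrywise-identical columns count as
agreeing — exclusion avoids biasing the fractions either way in a case the
agreement rule simply does not address.

## The synthetic world

Real replicate datasets of this kind are external downloads, so validation
runs on a generator (`generate_world()`) that reproduces the statistical
structure the method assumes, in the single-C2H2-ZF geometry:

* a contact model with one dominant key residue per binding-site position
  (contact frequency ≈ 0.9), at most one secondary contacter (≈ 0.2–0.4),
  and sub-threshold flanking positions, with keys running antiparallel to
  the binding site as in the zinc-finger recognition geometry;
* 200 distinct four-residue cores drawn from 8 residues per position —
  sparse enough that single-mismatch neighborhoods are informative but not
  dense, as in real core-sequence space;
* ground truth in which cores sharing the key residue at *j* share *j*'s
  truth column exactly, one Dirichlet(0.5) draw per (key residue, position)
  — concentration 0.5 gives informative, motif-like columns (a
  `secondary_jitter` option perturbs truth along secondary contacts for
  sensitivity analyses; the reference conditions keep sharing exact);
* two independent replicate observations, each column a multinomial
  resample of truth at 50 pseudo-sites — a modest effective depth typical of
  selection-based motif estimates;
* per replicate, an independent 20% of cores replaced by flat Dirichlet
  draws: failed experiments, the "less accurate for some proteins" regime
  the method exists to repair.

What passing on this world shows: the method moves two *independently*
smoothed noisy datasets toward their common truth (agreement gain ≫ loss,
failed cores recover, random-pairing and node-permutation controls stay
flat), and the two formulations select nearly the same agreeing columns.
What it does not show: performance under model mis-specification — real
interfaces have correlated contacts, position-dependent alphabets, docking
geometry changes at some cores, and inter-position dependencies within
binding sites, none of which the generator emulates.  The structural prior
here is exactly right by construction; on real data it is only
approximately right, and results there should be read from the original
datasets, not extrapolated from the simulation.

## Numerical and design choices

* **QP as a linear solve**: exact, deterministic, and O(n³) per position in
  the number of connected cores; the feasibility check makes the
  inactive-constraint argument verifiable at run time rather than trusted.
* **Normalization direction**: out-weights are normalized per node, as the
  per-protein constraint demands; the objective's double sum symmetrizes
  the directed weights implicitly, and we use them as printed rather than
  pre-symmetrizing.
* **Zero-weight edges are absent**, not stored: `M[i, j] = 1` at the
  differing position annihilates the edge at *j*.
* **Node permutation control** draws one independent bijection per graph
  (`share_permutation = TRUE` gives the shared-permutation variant).
* **Degenerate inputs**: an all-zero count column with zero pseudocount, a
  core shorter than the contacting-position count, a graph node missing
  from the dataset, and an empty core intersection are all hard errors;
  a binding-site position no base-contacting residue touches yields no key
  position and hence zero pair weights there.
* **Determinism**: both solvers are seed-free; every stochastic operation
  (world generation, random pairing, node permutation) takes an explicit
  seed and is reproducible from it.

## Reference study sizes

The packaged study (tests and `scripts/acceptance.R`) uses 200 cores, two
replicates, a QP α-sweep over 1…0.2 and an LPA grid over 0.1…0.9, with the
solver-vs-oracle comparison on ≤ 5-node instances and propagation residuals
checked on 500-node graphs.  These sizes exercise every code path at
desk scale; the algorithms themselves are dense-matrix implementations
adequate to a few thousand cores per dataset.

## Known limitations

* The generative maximum-likelihood formulation (joint multinomial
  likelihood with a coupling penalty) is documented in the README as
  motivation but not implemented; smoothing here happens after per-protein
  estimation, not simultaneously with it.
* No reverse-complement handling: all PWMs are assumed registered to a
  fixed interface orientation, as in core-sequence-resolved C2H2-ZF data.
* Inter-position dependencies (dinucleotide models) and alignment-based
  whole-motif similarity scores are out of scope.
* Contact maps arrive pre-aligned; the package does not parse structures or
  compute atomic distances.
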