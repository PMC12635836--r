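---
title: "Growing, fitting, and stress-testing generative connectome models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing, fitting, and stress-testing generative connectome models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectogen)
```

## The model

A generative network model (GNM) grows an undirected binary network on a
fixed set of spatially embedded nodes, one edge per step, starting from an
empty adjacency matrix. At each step every absent pair (i, j) is weighted
by a trade-off between wiring cost and a pairwise feature:

* **cost term** `exp(-eta * D_ij)` (or `D_ij^-eta` under power-law decay),
  where `D` is the Euclidean centroid distance in mm;
* **feature term** `F_ij^gamma`, where `F` in [0, 1] is either absent
  (spatial model), a static interregional similarity matrix, or the
  matching index of the growing network (the neighbourhood overlap of i
  and j, excluding i and j themselves), recomputed after every addition.

Each term is normalized by its extremum over *currently absent* pairs, and
the terms are combined additively with weight `alpha` or multiplied
(the multiplicative form has no `alpha`, and `gnm_params()` rejects one
rather than silently ignoring it). Weights become sampling probabilities
by simple normalization over absent pairs; present pairs have probability
zero. The per-pair probabilities are averaged over the steps at which the
pair was still absent, giving the mean connection probability surface used
by the distance-resolved diagnostics.

### Assumptions worth keeping in mind

* Wiring cost is Euclidean distance between node centroids. Real axonal
  trajectories are longer than straight lines, but the two are strongly
  correlated at this scale and rank-based statistics are unaffected by
  monotone distortions.
* Growth is density-matched: the model stops at exactly the target's edge
  count, so all model-target comparisons are between equal-size edge sets.
* Networks are binary, undirected, and hollow; weighted generation is out
  of scope.

## Tunable parameters

| parameter | meaning | default box | notes |
|---|---|---|---|
| `eta` | distance-penalty strength (1/mm for exponential) | [0, 2] exponential; [0, 10] power-law | 0 disables the cost term |
| `gamma` | feature exponent (dimensionless) | [-20, 200] static features; [-10, 10] matching | negative values reward dissimilarity |
| `alpha` | feature-term weight (additive only) | [0, 10] | 0 reduces to the spatial model |

Two numerical choices make extreme exponents safe. First, normalized
powers are evaluated in log space — `exp(gamma * (log F - log F_ref))`
with `F_ref` the max (`gamma > 0`) or min (`gamma < 0`) over absent
pairs — which is algebraically identical to `F^gamma / max(F^gamma)` but
cannot underflow even at `gamma = 200`. A property test checks agreement
with naive evaluation to a relative 1e-9 wherever the naive form is
representable. Second, features are floored at 1e-6 before powering, so
the matching model's all-zero first step is well defined for any `gamma`;
at that step every (clamped) feature value is equal, the normalized
feature term is constant, and under the multiplicative form the step-1
probabilities coincide with the spatial model's (a frozen test asserts
this to 1e-6). The clamp is this package's choice for an undefined corner
of the standard formulation.

Sampling is one exact multinomial draw per step from the full probability
vector — no top-k shortcuts, no tie-breaking heuristics. For spatial and
static-feature rules the normalizing constant is the only thing that
changes between steps, so the whole edge sequence is distributed as a
weighted sample without replacement; `grow_network(method = "successive")`
draws it in one call and is used inside the optimizer, while the default
sequential method retains the full trace. A debug flag asserts, at every
step, that probabilities over absent pairs sum to 1 within 1e-12 and that
the O(n)-updated matching matrix equals a from-scratch recomputation
exactly.

## Fit statistics

`max_ks()` scores a network pair by the maximum of four two-sample
Kolmogorov–Smirnov statistics: degree, binary local clustering, Brandes
betweenness, and connection length. The KS statistic is computed on
right-continuous empirical CDFs evaluated at all pooled sample points, so
ties (ubiquitous in degree vectors) are handled exactly. Betweenness is
left unnormalized: both networks share a node count, and the KS statistic
and all correlations are invariant to the common normalization, so the
choice is observationally neutral (it is stated here for reproducibility).

Topography is scored separately: connection recovery `R` (fraction of
target edges present in the model), Jaccard overlap, per-bin recovery and
false-discovery rate in short (< 30 mm), mid (30–90 mm), and long
(>= 90 mm) distance bins, and the Spearman correlation between degree
sequences.

`alt_measures()` implements four complementary similarity measures. Two
sets are deliberately kept behind a registry because their exact
constituents are a design choice rather than a fixed convention: the
global summaries entering `TND` (global clustering, global efficiency,
Louvain modularity with a fixed internal seed, degree assortativity,
z-scored across the compared networks — pass `catalog` to anchor the
z-scores on a wider set) and the nodal features entering `TF_diff`
(degree, clustering, betweenness, mean incident edge length, chosen for
symmetry with the KS components). `max_RMSE` uses harmonic closeness — a
closeness variant that stays defined on disconnected graphs — alongside
degree, clustering, and mean incident length, each min-max rescaled
jointly across both networks. Where a per-edge quantity must become nodal
(the "connection length" entry of `max_rd`/`max_RMSE`), the mean incident
edge length is used, with isolated nodes flagged and set to 0. Undefined
components (zero variance, undefined assortativity) are dropped and
flagged, never silently zeroed.

## Parameter optimization

`optimize_gnm()` fits parameters by Voronoi-tessellation preferential
resampling: 2,000 uniform points in the box, then four rounds of 2,000
points each drawn from the Voronoi cells of all evaluated points with
probability proportional to `score^(-beta)`, `beta` stepping through 0.5,
1, 1.5, 2 (10,000 evaluations in total under the standard budget; the
`"small"` and `"tiny"` presets scale this to 1,500 and 120 evaluations
for desk-scale studies, and the suite's recovery checks run at 100–150
nodes for the same reason). Each point is evaluated by growing **one**
stochastic network and scoring max(KS) against the target, or the mean of
per-target max(KS) over an ensemble; growth seeds vary across points and
are recorded per evaluation, and `n_realizations` exposes
variance-smoothing for anyone who wants it (default 1).

One identifiability caveat matters when designing recovery experiments:
`eta` multiplies distances in their native units. On a 100 mm hemisphere,
every `eta` above roughly 0.5 concentrates the exponential rule so hard
that growth collapses onto the same quasi-deterministic shortest-edge
network — the max(KS) objective is then flat at its noise floor across
most of the `[0, 2]` box and the generating `eta` is unrecoverable. The
package's parameter-recovery and distance-decay studies therefore use a
compact 10 mm embedding, where `eta = 1` sits mid-way up a well-shaped
objective (a 21-point grid oracle shows a clear V with its minimum near
the generating value). Studies that only need *a* strong distance
penalty — the planted-hub fits, the rewiring analysis — keep the 100 mm
hemisphere.

Two details are this package's own resolutions of genuinely open design
points. Distances for cell membership are computed after rescaling every
active parameter to the unit interval — without this, `gamma`'s range
(width 220) would dominate the tessellation and `eta` would be effectively
unsearched. And sampling *within* a drawn cell, which no closed form
provides, is done by rejection: uniform box candidates are kept when their
nearest evaluated point is the drawn cell's seed (exact Voronoi membership
in any dimension), with a Gaussian fallback (sd = 5% of each box width,
clipped) for sliver cells that survive 1,000 candidate batches. Scores are
floored at 1e-6 before the `-beta` power so a perfect fit cannot blow up
the allocation.

## Synthetic data: what it emulates, and what it does not

`make_embedding()` places nodes on a hemispheric shell (or sheet/cloud)
of configurable scale — 100 mm throughout the test suite, giving pair
distances up to ~200 mm, comparable to a human hemisphere.
`plant_target()` samples background edges with probability proportional
to `exp(-lambda * D)`; `lambda = 0.1`/mm is used as the standard
condition, a decay strong enough that unaided cost-penalising models face
the same long-range scarcity tractography networks show. On top of the
background, a configurable fraction of edges (10% in the standard planted
condition) is planted between hubs placed by farthest-point sampling, all
longer than 90 mm — a synthetic stand-in for the empirically observed
long-range hub scaffold. `make_cohort()` derives individual-like variants
by length-matched edge relocations, so cohort overlap is controlled
exactly.

Nodal features are made spatially autocorrelated exactly the way the
random-similarity model demands: one uniform(0, 1) draw per node, then
five synchronous rounds in which each node takes the mean of its
neighbours' values (all means computed before any update), twenty
independent columns, pairwise Pearson correlation of node profiles
rescaled to [0, 1]. Real cortical surfaces provide a vertex-adjacency
graph for this smoothing; synthetic embeddings have no mesh, so the
symmetrized 6-nearest-neighbour graph on node coordinates stands in for
"adjacent on the surface" — it preserves the local-averaging semantics on
any embedding and is the only place the neighbour graph is used.
Smoothing provably never increases a column's variance on these graphs
(property-tested across 200 embeddings).

Orientation of the similarity rescaling is exposed as a flag. Taken
literally, converting a correlation to a Pearson distance and rescaling
to the unit interval yields a *dissimilarity*; but a positive feature
exponent only rewards similar regions if large values mean "alike", so
the default is the similarity orientation `F = (r + 1) / 2`, with
`orientation = "distance"` giving the literal reading (`(1 - r) / 2`,
exactly `1 - F`). Neither is asserted to be the canonical choice; the two
differ only by `gamma`'s sign convention.

What passing tests on these synthetics do **not** show: real connectomes
have inter-hemispheric homotopy, geometric constraints from sulcal
folding, distance-dependent feature assortativity, and acquisition biases
against long streamlines — none of which the generator emulates. Results
here demonstrate properties of the models and measures, not of any
empirical brain.

## Rewiring null models

`rewire_once()` quantifies how fast the fit statistics react to edge
displacement. Every *original* edge is processed exactly once (random
order, or by ascending/descending length with randomized ties), deleted,
and relocated to a pair chosen from the pairs absent in the *original*
network, minus already-used targets — uniformly, or minimizing/maximizing
the absolute length difference. Vacated slots never re-enter the pool.
This interpretation (original edges, original non-edges only) is a
deliberate tightening of the looser "existing connections" wording: it
guarantees termination and makes the overlap law exact — after t rewires,
overlap with the original is `(m - t) / m`, asserted without tolerance in
the tests. The possible divergence (a later rewire refilling a vacated
slot) would only matter late in the pass. Checkpoints default to every
`max(1, floor(m / 100))` rewires; 30 runs and a pointwise mean curve
reproduce the qualitative signature that the maximum-KS curve rises
steeply and is led by the clustering component through the first half of
the pass.

## Distance-resolved diagnostics

* `distance_threshold_degree()` correlates degree computed from edges
  below (or at/above) each threshold with full degree; below/above are
  exact complements, and zero-variance thresholded degrees are flagged
  invalid rather than reported as 0.
* `probability_vs_distance()` emits the full pair table (distance, mean
  probability, target-edge indicator) plus its Spearman summary.
* `sliding_window_precision()` slides a ±5 mm window over *all* node
  pairs (target non-edges included — the equal-probability null needs
  them), selects the top `ceiling(f * n)` pairs by mean probability (ties
  randomized under the supplied seed; the ceiling guarantees any positive
  fraction selects at least one pair), and reports precision against the
  in-window base rate. Window centres default to a 1 mm grid spanning the
  observed distances, and windows with fewer than 10 pairs are flagged —
  both are package choices to tame 0/1 noise at the distance extremes.
* `formed_edge_fdr()` bins *model* edges and reports the per-bin fraction
  absent from the target.

All distance bins are half-open `[lo, hi)` and default to
`{0, 30, 90, Inf}` mm.

## Degenerate inputs and edge cases

Empty targets, all-zero weight vectors, isolated nodes under smoothing,
zero-variance node profiles and degree vectors, infeasible hub
specifications, exhausted rewiring pools, and non-covering bin grids all
raise typed errors or explicit flags — never silent zeros. Duplicate
coordinates are rejected at embedding construction (zero off-diagonal
distance would break the power-law decay and the k-NN graph).

## Known limitations

* Only the matching index is implemented as a dynamic topological
  feature; the wider family of topological rules plugs in behind
  `feature_source` but is not shipped.
* `TND`'s z-scoring over just the compared pair collapses magnitude
  information (each differing summary contributes a fixed amount); supply
  a `catalog` of reference networks for a scale-anchored version.
* The experiment driver's staleness detection is digest-based and
  per-stage; it does not track fine-grained dependencies inside a stage.
* Growth is O(steps x pairs); the practical ceiling on one CPU is a few
  hundred nodes for matching-model fitting.
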