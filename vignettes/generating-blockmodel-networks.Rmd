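---
title: "Generating blockmodel-structured networks from triad types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating blockmodel-structured networks from triad types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadnet)
```

## The question the package addresses

A blockmodel reduces a directed network to a small image: clusters of
structurally equivalent units (units with identical in- and out-neighbour
patterns) and, for every ordered pair of clusters, a block that is either
*complete* (all arcs present) or *null* (no arcs). Seven classical images are
built in: cohesive (complete diagonal), symmetric and asymmetric
core-periphery, and hierarchical and transitivity structures with either
null or complete diagonal blocks. A network that realizes its image exactly
is an *ideal* network.

The package asks: can such global structures be grown from purely **local**
information — the counts of the 16 directed triad types (the Holland-Leinhardt
M-A-N census) — without any knowledge of cluster memberships or unit
attributes? Two generators answer it:

* a deterministic **relocating-links** (RL) rewiring scheme that swaps an
  arc with a non-arc whenever the move brings the triad-count vector strictly
  closer to a target, and
* a **fixed-coefficient exponential random graph** (ERGM) Metropolis-Hastings
  sampler in which each triad statistic carries a fixed weight (+2 if the
  triad type is allowed under the blockmodel, −2 if forbidden).

Success is scored by fitting the pre-specified blockmodel back to each
generated network and comparing its criterion value with that of a
density-matched uniform random network, summarized as the mean improvement
value (MIV).

## Triad machinery

`triad_census()` counts the 16 types over all `choose(n, 3)` triples by a
64-entry dyad-code lookup table; `census_delta()` updates the census after
arc toggles by revisiting only the `n − 2` triples that contain both
endpoints of a toggled dyad. Both share one orientation convention (021D =
one sender to two receivers, 021U = the reverse; 111D = the lone asymmetric
arc points into the mutual dyad), verified in the test suite against
`igraph::triad_census()` and by the arc-reversal duality (reversing every
arc must swap the U/D variants and fix all other labels).

A triad type is **allowed** for a blockmodel when its count in the ideal
network is positive, and **forbidden** when that count is zero
(`classify_triads()`). The classification is exact — computed from the ideal
census, not from sampling. The **A-measure** (`a_measure()`) is the ratio
between a type's ideal count and its mean count over density-matched
randomized networks; it quantifies how strongly the blockmodel, rather than
density alone, favours the type. Because the reference distribution
approaches the ideal network as the level of errors shrinks, the A-measure
tends to 1 from above as LE decreases and is largest for fully randomized
references.

Six types (012, 111D, 111U, 030C, 120C, 210) are forbidden under all seven
default images — single arcs in otherwise-null triads and cyclically mixed
patterns are incompatible with complete/null block structure.

**Selected subsets.** The reduced "selected allowed" sets equal the allowed
sets except that 021C is dropped for the hierarchical image without diagonal
blocks and 300 for the transitivity image with diagonal blocks. Reduced
*forbidden* sets come from sensitivity analyses that are inherently
study-specific; rather than fix arbitrary members, the package defaults
`selected_forbidden` to the full forbidden set (with a message) and lets the
user supply a reduction explicitly. The selection mechanism itself
is pluggable through the `selected_forbidden` argument.

## Level-of-errors perturbation

`perturb()` interpolates between an ideal network (LE = 0) and a fully
randomized network of the same density (LE = 1) by relocating

\[ k = \operatorname{round}\bigl( \mathrm{LE}\cdot(m - m^2/(n^2-n)) \bigr) \]

arcs from complete-block to null-block positions. The form of the constant
is pinned by two boundary conditions — no relocations at LE = 0, and equal
complete- and null-block densities at LE = 1 — which determine it uniquely.
Each relocation creates exactly one missing-arc error
and one surplus-arc error, so the criterion under the true partition is
`2k`, which the tests exploit as an exact oracle. Rounding is
nearest-integer with ties up.

## The relocating-links generator

`generate_rl()` starts from a density-matched uniform random digraph
(`initial_network()`) and, for `iters` iterations (default 6000), removes a
uniformly chosen arc and adds a uniformly chosen non-arc. The move is kept
iff the comparison ratio

\[ CR = \frac{\sum_i (T^{cur}_i - T_i)^2}{\sum_i (T^{prop}_i - T_i)^2} \]

exceeds 1, i.e. iff the squared distance of the statistic vector from the
target strictly decreases. Two numerical decisions are deliberate:

* **Orientation.** The ratio is oriented with the *current* distance in the
  numerator, so CR > 1 means the proposal is strictly closer. The opposite
  orientation is occasionally written for such ratios but would accept
  distance-*increasing* moves, contradicting the acceptance semantics.
* **Ties.** `CR = 1` (including the 0/0 case) is rejected. Strict
  improvement makes the distance trace non-increasing and the descent
  finite. Accepting ties (plateau drift) was evaluated and does not change
  the attained structure, so the simpler rule is kept.
* A proposal with zero distance is always accepted (`CR = Inf`).

Arc count is invariant by construction, so the generator explores the
fixed-density ensemble. One practical property matters for interpreting
results: with uniform proposals the acceptance rate decays sharply as the
network approaches the target, so the structure attained at a fixed
iteration budget is a point on a slow convergence curve, not an optimum.
At the default 6000 iterations the generated networks are recognizably but
not perfectly blockmodel-structured; several-fold longer runs continue to
improve them. The iteration budget is therefore a first-class parameter of
any study, and `scripts/acceptance.R` reports what the default budget
actually achieves.

## The fixed-coefficient ERGM sampler

`sample_ergm()` runs Metropolis-Hastings with acceptance probability
`min(1, exp(theta . (g(proposal) − g(current))))`. Both proposal kernels are
symmetric, so no proposal-ratio correction is needed:

* `mode = "fixed"`: swap a uniform arc with a uniform non-arc (arc count
  conserved exactly);
* `mode = "free"`: toggle a uniform ordered dyad; density is governed by the
  model, normally through an `edges` term.

Coefficients are not estimated — maximum-likelihood fitting on
near-ideal networks is ill-conditioned because triad counts are strongly
collinear — but fixed at +2 for allowed and −2 for forbidden statistics
(`blockmodel_ergm_model()`). Chains start from a randomized ideal network
and return the state after `iterations` steps (default 10000, burn-in 0):
the object of interest is the finite-time generative behaviour, not the
stationary law. The sampler's correctness *as* an MCMC is nevertheless
verified exactly: on 3 units the empirical state distribution over all 64
digraphs matches the model law by chi-squared test.

**Density tuning.** For free-density runs, `tune_edges()` bisects on the
edges coefficient until the mean density of 30 sampled networks lies within
±0.05 of the ideal density. The default bracket is wide ([−40, 100]):
with a strongly penalized three-paths statistic, a sparse network resists
growth (an arc added near the empty state converts ~2(n−2) rewarded 003
triads into penalized 012 triads), and compensating edges coefficients of
order 30 are genuinely needed.

**Repairing the hierarchical blockmodel.** Triads alone cannot pin down the
hierarchical image with null diagonal blocks: its allowed types (003, 021U,
021D, 021C) occur in any mixture of upward and downward arcs, and generated
networks carry arcs in both off-diagonal directions.
`hierarchical_fix_model()` adds the count of directed **three-paths**
(three-trails: ordered sequences of three distinct arcs a→b→c→d, unit
revisits permitted — the definition that matches cluster sequences such as
1→2→3→2) with coefficient −2, which eliminates chains of length three and
with them the downward arcs; and raises one 021-chain coefficient (021C by
default, 021D selectable) to +4 to recover three levels rather than two.
Under this model the ideal hierarchy is strongly metastable — a chain
started at the ideal network stays at criterion 0 — while chains from
randomized starts must nucleate the structure, which most but not all
achieve within the default budget.

## Blockmodel fitting and the improvement value

`criterion()` counts inconsistencies with a pre-specified image: arcs inside
null blocks plus missing ordered pairs inside complete blocks.
`fit_prespecified()` minimizes it over partitions with K non-empty clusters
by repeated steepest-descent local search (single-unit moves plus pairwise
exchanges; moves that would empty a cluster are barred), from uniform random
restarts (default 100). Ties between equally improving steps are broken by a
seeded random scan order, keeping runs reproducible; exchanges are included
because only the attained minimum matters. The search is validated against
exhaustive enumeration of all two-cluster partitions at n = 8.

The **mean improvement value** of k generated networks is

\[ \mathrm{MIV} = 1 - \frac{1}{k}\sum_i P^m_i / P^r_i, \]

with \(P^m_i\) the fitted criterion of network i and \(P^r_i\) that of an
independently randomized network of the same density. MIV = 1 iff every
generated network fits perfectly; random inputs give mean 0; negative values
mean worse-than-random. A randomization that itself fits perfectly
(\(P^r = 0\), possible only for very small networks) is redrawn up to five
times and then dropped with a warning. One randomization per generated
network is used — a deliberate variance/cost trade-off that keeps each MIV
cell cheap at the price of extra replicate-level noise.

## Study conditions and problem sizes

`run_study()` crosses blockmodel types, triad-set choices and generators.
The defaults are the package's reference study conditions: networks of 24
units,
cluster sizes 8/8/8 (three-cluster images) or 8 core / 16 periphery
(core-periphery), 6000 RL iterations, 10000 sampler iterations, 100 fitting
restarts, 50 networks per cell (`scale` rescales this; the acceptance
script uses 10 networks per cell, and the test suite smaller grids still).
Equal three-cluster sizes are the documented default; all sizes are
configurable.

## What the synthetic benchmarks do and do not show

All inputs are generated internally: ideal networks, their level-of-errors
perturbations, and uniform fixed-arc-count randomizations. These capture
exactly one departure from ideal structure — uniformly misplaced arcs. Real
networks deviate differently (degree heterogeneity, reciprocity bias,
missing data), so passing tests demonstrate correctness of the machinery
and reproducibility of the simulation design, not performance on empirical
data. The MIV is also not comparable across network sizes, and with the
RL generator and all-allowed targets it is mildly optimistic because
cluster-size information is embedded in the target counts.

## Known limitations

* The RL rule is greedy; without restarts or annealing it can stall in
  local optima, visibly so for the dense symmetric core-periphery image.
* Fixed ±2 coefficients make the all-triads free-density model unstable
  (the empty and complete networks are strong attractors); free-density
  runs should start from randomized ideal networks, as the default does.
* Only structural equivalence (complete/null blocks) is supported; regular
  and valued block types are out of scope, as is coefficient estimation.
* Images with more than three clusters are accepted but have not been
  benchmarked; the reference conditions cover two and three clusters.
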