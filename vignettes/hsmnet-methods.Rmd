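---
title: "Detecting hierarchical social modularity in covisit data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hierarchical social modularity in covisit data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsmnet)
```

## The inference problem

Some mammal societies are built in nested layers: small social units
combine into larger ones, which combine into larger ones again, with a
roughly constant size multiplier between adjacent layers. Demonstrating
such *hierarchical social modularity* from field data is hard when the
units range over terrain where direct observation of inter-unit
interaction is impossible. One workable design observes a resource hotspot
— for western lowland gorillas, a mineral-rich forest clearing ("bai") —
and records which social units (groups or solitary males) visit on each
day. Units that repeatedly appear on the same days are plausibly
affiliated; the analytical problem is to turn a units-by-days presence
matrix into defensible statements about tiers of social structure.

`hsmnet` implements that full chain: association indices, permutation
null models, dendrogram-based tier detection, multi-resolution modularity,
tier-size scaling, and kinship/consistency regressions, together with a
synthetic generator that plants known two-tier structure so every stage
can be validated end to end.

## Association indices

Let `T` be the number of observation days, `v_i` unit *i*'s visit count
and `k_ij` the number of days both *i* and *j* visited (a *covisit*).

**Simple ratio (SR).** `SR_ij = k_ij / (days at least one visited)` — the
day-level Jaccard coefficient of the two visit-day sets, the standard
gambit-of-the-group index at one-day sampling resolution. It is simple
and widely comparable but can assign spuriously high values to rarely
seen units.

**Binomial probability (BP).** The upper-tail probability
`p_ij = P(X >= k_ij)` with `X ~ Binomial(T, (v_i/T)(v_j/T))`: how likely
the observed covisit count would be if both units visited independently
at their average rates. A small tail means covisiting far beyond chance.
The stored association value is `1 - p_ij` so both indices read "bigger =
closer"; the tail itself feeds the clustering below. By conditioning on
each unit's visit rate the BP index is robust to exactly the artefact
that hurts SR.

With `rate_adjust = TRUE` the per-day covisit probability is modulated by
the squared relative daily attendance, rescaled to preserve the mean, and
the tail is computed from the exact Poisson-binomial distribution
(dynamic-programming convolution in C++, summing the upper tail directly
so tiny tails keep full relative precision). This corrects for
population-wide visitation waves — seasonality makes *every* pair covisit
more on busy days, which is environment, not affiliation. With constant
attendance the adjusted index equals the plain one to machine precision.

## Null models

Two nulls match the two indices' conditioning:

* **SR — data-stream permutation.** Checkerboard swaps of the presence
  matrix preserve every unit's visit count *and* every day's attendance
  while destroying pairwise association. Ensembles are drawn from one
  sequential chain with thinning (default 500 successful swaps between
  samples; burn-in and thinning are configuration, since no canonical
  values exist). The chain counts *successful* swaps; on margin classes
  where the number of swappable 2x2 submatrices varies between states
  this introduces a slight non-uniformity, which is the standard
  behaviour of this permutation lineage.
* **BP — visit resampling.** The BP null hypothesis conditions only on
  unit visit counts, so each null sample redraws every unit's visit days
  uniformly at random (same `v_i`, days free) and recomputes the index.

Empirical p-values use the add-one convention
`(1 + #extreme) / (1 + n)`: never exactly zero, ties count as extreme.

## Tier detection from the dendrogram

BP tails are transformed to distances `d = p^(2/3)` and clustered by
UPGMA (average linkage). The 2/3 power is not cosmetic: it makes the
*cumulative bifurcation curve* — merge count against merge height — of
null-model dendrograms approximately linear (null mean R² ≈ 0.99 in the
stage-3 analysis script), so a gradient change in the real curve can be
read as a transition between organisational levels rather than an
artefact of the tail distribution. The direction of the transform
(tail-as-distance, small tail = close) is pinned here because it is the
reading that produces linear null curves.

The **knot scan** computes local gradients between consecutive distinct
heights (ties share one step), then for every split with at least 5
gradients per side compares the two gradient samples with a two-sample
Wilcoxon rank-sum test (exact when both sides have ≤ 25 untied values,
normal approximation with tie correction otherwise). The knot is the
split with minimum p. Cutting the dendrogram strictly below the knot
yields the tier-1 partition; units first joining at or above the knot
stay singletons.

**Known limitation.** Reporting the *minimum* p over all candidate
splits without a multiplicity correction — as the procedure is defined —
is anticonservative under the null: on homogeneous synthetic curves
about 30% are flagged at α = 0.05. Genuine two-gradient curves are
detected essentially always and with far smaller p (< 10⁻³), so the
statistic discriminates well, but a knot p-value near the threshold
should not be read as a calibrated error rate. The test suite asserts
the distributional version of this statement rather than pretending the
scan is exact.

## Modularity and the resolution sweep

Tier-2 modules come from Louvain optimisation of weighted modularity

&nbsp;&nbsp;`Q(γ) = Σ_c [ w_c/W − γ (s_c / 2W)² ]`

via `igraph::cluster_louvain`, followed by a single-node local-move
refinement pass (multi-level aggregation can freeze assignments that one
later move would improve; refinement guarantees the returned partition is
at least move-optimal). Node order is shuffled per restart (default 10,
best Q kept); with a seed the result is deterministic. On all ≤ 8-node
fixtures tried, 100 restarts plus refinement attain the brute-force
optimum over every set partition.

Significance comes from optimising each null matrix identically and
taking the empirical p. The resolution sweep repeats this on the SR
network for γ from 0 to 2 (default step 0.01; the analysis scripts use
0.02 to keep run time proportionate), reusing one null ensemble across
resolutions. Significant p-troughs mark organisational scales. On real
gorilla-type data two separated troughs appear (coarse modules and small
first-tier associations); on the strong-signal synthetic defaults the
p-curve floors across the whole γ ≥ 0.9 range, merging both scales into
one trough whose extremes — from ~24 units down to ~2 units per module —
bracket the two planted tiers. BP-based sweeps are available behind a
flag but default off: BP null p-values are too extreme to vary usefully
at feasible ensemble sizes.

**Resolution limit.** At γ = 1, merging two modules with between-module
weight `w_12 > s_1 s_2 / 2W` *raises* Q. Because baseline covisits give
every pair a positive expected SR, small planted modules are sometimes
absorbed by a neighbour even when recovery of all other modules is
exact: the optimiser is right and the γ = 1 landscape is the constraint.
Tier-2 recovery on synthetic defaults is therefore bimodal — ARI 1.0 in
roughly half the runs, ~0.83–0.89 (one merge) otherwise, with the median
over seed sets sitting at or above 0.9. This is precisely why the sweep,
not single-γ modularity, is the instrument for finding *multiple* scales.

**Cross-method consistency** is checked by logistic regression of tier-2
co-membership on tier-1 co-membership over all unit pairs. Dyads are not
independent, so the Wald z is a descriptive statistic (no MRQAP
correction), as is conventional for this check. Under strong nesting the
2x2 pair table often separates completely (an infinite-slope condition,
flagged as such); the Haldane–Anscombe corrected z (+0.5 per cell) is
reported alongside as the finite fallback.

## Scaling and kinship

The tier-size table assembles mean individuals per social unit at each
level: 1 (individuals, size 1 by definition), 3 (groups/solitaries),
4 (tier-1 clusters), 5 (tier-2 modules); levels 2, 6 and 7
(mother–offspring units, sub-population, population) cannot be derived
from a covisit stream and enter only as explicit configuration — the
package refuses to fabricate them. `scaling_fit` regresses `log(size)` on
level; `exp(slope)` is the scaling ratio, exact on geometric series. With
several populations, either pool with population intercepts or average
sizes per level first (the default for a combined ratio).

Kinship analysis consumes *given* binary relatedness between silverbacks
(1 = half-siblings or closer) and regresses tier-2 co-membership on it,
reporting Wald z, the separation flag, and the fraction of same-module
pairs that are related. The same dyadic-independence caveat applies.

## The synthetic generator

The generator emulates the study design: `n_units = 48` (27 groups, 21
solitary males), `T_days = 730` (one 2-year dataset), units dropped below
8 visits, seasonal attendance with amplitude 0.3 on an annual sine.
Planted structure is literal, not copula-based: each tier-1 cluster and
each tier-2 module draws a latent daily "excursion"
(`excursion_prob = 0.3`), and a unit's visit probability
`base_visit_rate × mult_i × s_t` is multiplied by `within_tier1_boost =
10` and/or `within_tier2_boost = 6` when its cluster's and/or module's
excursion fires. Choices made once, on design grounds:

* `base_visit_rate = 0.03`/day with Gamma(shape 4) per-unit multipliers:
  baseline ~22 visits per 2 years, boosted units visiting every few days
  — gregarious-end field rates, deliberately generous so that recovery
  power, not sample starvation, is what the tests measure.
* Boosts 10/6 with excursion probability 0.3 are the "strong signal"
  regime: within-cluster SR several times the between-module baseline;
  design-phase calibration put median tier-2 ARI ≈ 0.93 and knot
  detection at 100% before the acceptance checks were written.
* Tier-1 cluster sizes are 1 + Poisson(mean − 1): singletons are real
  social structure (units that pair with nobody). Tier-2 module sizes use
  gamma-weight apportionment with every module at least half the mean: a
  planted "module of ~8 units" of size 1–3 would contradict the regime
  being emulated and is provably invisible to γ = 1 modularity (the
  resolution limit above), i.e. it plants structure the method cannot
  represent rather than testing recovery.
* Kinship: related with probability 0.35 within modules, 0.05 between.
* Visit probabilities pushed past 1 by stacked boosts are clamped with a
  logged count (~7% of unit-days at defaults).

What the generator does *not* emulate: demographic turnover (units are
atomic and permanent), unmonitored days, spatial structure within the
clearing, and observation error in unit identification. Passing recovery
tests therefore show that the chain detects the *kind* of structure it
targets at field-plausible sizes — not that any particular empirical
dataset has that structure.

With boosts set to 1 the generator is the inference's own null, which is
what the calibration check exploits: over 200 structureless replicates
(20 units, 180 days, 200 permutations each — sizes chosen to make a
200-replicate calibration proportionate), the rejection rate of the
modularity p at α = 0.05 must lie inside the binomial 95% interval
around 0.05.

## Numerical and degenerate-input choices

* BP tails: exact `pbinom` upper tails (plain) and exact Poisson-binomial
  convolution (adjusted); no normal approximations anywhere in the index.
* Pairs never observed (`x + y_i + y_j = 0`) get SR 0; `k = 0` gives BP
  tail 1 (association 0); units with zero visits are an error — filter
  first.
* UPGMA ties follow `stats::hclust` conventions; the tier-1 cut at height
  *h* groups exactly the pairs with cophenetic distance < *h*.
* Mantel Z is the Pearson correlation of off-diagonal upper triangles
  under simultaneous row/column relabeling; constant matrices are an
  error, not a silent NA.
* All stochastic operations take explicit seeds; ensembles record seed,
  method and thinning for reproducibility.

## Problem sizes used by the packaged analyses

The analysis scripts and acceptance run use: 20 replicate studies at the
default 48-unit/730-day conditions for recovery medians; 200 (tests) or
100 (script) structureless replicates with 200-permutation ensembles for
calibration; 200-permutation ensembles for headline modularity p-values;
a 0.02-step γ grid with a 100-matrix ensemble for the sweep; 1000
permutations for Mantel tests. These sizes were chosen so the complete
validation remains proportionate on a single CPU while keeping every
Monte-Carlo standard error well below the effect sizes being asserted.
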