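# hsmnet

Inference of **hierarchical social modularity** from covisit records — for
behavioural ecologists and social-network analysts working with
gambit-of-the-group data collected at a shared resource hotspot (e.g.
gorilla groups and solitary males visiting a forest clearing, where the
only observable inter-unit "interaction" is being there on the same day).

From a units-by-days presence matrix the package infers nested social
tiers and quantifies their statistical support:

1. **Association indices.** The simple-ratio index
   `SR_ij = x / (x + y_i + y_j)` (day-level Jaccard of visit-day sets) and
   the binomial-probability index `p_ij = P(X ≥ k_ij)`,
   `X ~ Binomial(T, (v_i/T)(v_j/T))` — the upper-tail probability of the
   observed covisit count under independent visiting, optionally computed
   from the exact Poisson-binomial distribution after adjusting each day's
   covisit rate for population-wide attendance fluctuation.
2. **Null models.** Data-stream permutations (checkerboard swaps
   preserving unit visit counts and daily attendance) for SR;
   visit-count-conditioned resampling for BP; add-one empirical p-values.
3. **Tier-1 detection.** UPGMA clustering of transformed BP tails
   `d = p^(2/3)` (the transform that linearises null bifurcation curves),
   a Wilcoxon rank-sum *knot* scan for the gradient change in the
   cumulative-bifurcation curve, and a dendrogram cut below the knot.
4. **Tier-2 detection.** Louvain modularity
   `Q(γ) = Σ_c [w_c/W − γ(s_c/2W)²]` with restarts and single-node
   refinement, empirical p-values against null ensembles, and a resolution
   sweep over γ ∈ [0, 2] whose p-value troughs expose multiple
   organisational scales.
5. **Scaling & kinship.** The log-linear fit of mean unit size across
   social levels whose `exp(slope)` is the tier-to-tier scaling ratio, and
   dyadic logistic regressions for cross-method consistency and for
   kinship structure of module membership.
6. **Synthetic data.** A generator that plants two nested tiers in
   realistic visit streams (heterogeneous rates, seasonality, latent
   shared "excursions"), with ground truth for recovery scoring — every
   stage of the chain is validated against it.

## Worked example

```r
library(hsmnet)

# simulate a 24-unit, one-year covisit study with planted two-tier structure
cfg <- generator_config(n_units = 24, T_days = 365)
truth <- generate_population(cfg, seed = 42)
visits <- simulate_visits(truth, seed = 43)
pm <- filter_min_visits(build_presence(visits), min_visits = 8)

sr <- simple_ratio(pm)
bp <- binomial_probability(pm)
sr
#> SR association matrix: 24 units, mean off-diagonal 0.1403

# tier-2 modules: Louvain modularity against 99 data-stream permutations
ens <- null_ensemble(pm, "SR", n = 99, seed = 44)
mod <- modularity_p(sr, ens, seed = 45, units_info = truth$units_info)
mod
#> Louvain at gamma = 1.00: Q = 0.105 (3 modules, p = 0.01)

# tier-1 clusters: UPGMA on transformed BP tails, knot scan, cut
dend <- upgma(bp_distance(bp))
knot <- detect_knot(bifurcation_curve(dend))
tier1 <- cut_tier1(dend, knot$d_knot, truth$units_info)
tier1
#> tier-1 partition: 13 clusters over 24 units (mean 1.85 units, 7.5 individuals)

# scaling ratio across the detected levels
tab <- suppressWarnings(tier_sizes(tier1, mod$partition, truth$units_info))
scaling_fit(tab)
#> scaling ratio = 2.29 (R^2 = 0.962, p = 0.0189, 4 points)

# score against the planted truth
str(recovery_report(truth, tier1 = tier1, tier2 = mod$partition, knot = knot))
#> List of 4
#>  $ tier1_ari       : num 0.934
#>  $ tier2_ari       : num 1
#>  $ knot_significant: logi TRUE
#>  $ d_knot          : num 0.000347
```

Reading the output: the observed network's modularity (Q = 0.105) beats
all 99 permutation nulls (p = 0.01, the add-one floor), and the three
recovered modules match the planted tier-2 partition exactly
(ARI = 1). The knot scan finds a significant gradient change in the
bifurcation curve; cutting there yields 13 first-tier clusters averaging
1.85 units — the planted pair scale — and mean unit sizes across the four
detectable social levels grow by ≈ 2.3× per level.

## The analysis workflow

`analysis/` contains the study as numbered, narrative scripts, each a
thin driver over the package functions, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # synthetic population + 2x730-day visit stream
Rscript analysis/02_associations.R    # presence, SR/BP indices, Mantel stability
Rscript analysis/03_hierarchy.R       # UPGMA, bifurcation curve, knot, tier-1 cut
Rscript analysis/04_modularity.R      # Louvain + nulls, resolution sweep, consistency
Rscript analysis/05_scaling_kinship.R # tier-size scaling fit, kinship regressions
Rscript analysis/06_recovery.R        # ARI and scaling error vs planted truth
```

See `vignettes/hsmnet-methods.Rmd` for the model, its assumptions, the
generator's design and known limitations (knot-scan anticonservatism,
the γ = 1 resolution limit).

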