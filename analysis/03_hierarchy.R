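#!/usr/bin/env Rscript

# Stage 3: hierarchical clustering and tier-1 detection.
#
# Clusters the first-period BP association matrix by UPGMA on transformed
# tail probabilities (d = p^(2/3), chosen so null bifurcation curves are
# linear), extracts the cumulative-bifurcation curve, scans it for a
# significant gradient change (the knot marking the tier-1/tier-2
# boundary), and cuts the dendrogram below the knot into first-tier
# clusters. Also contrasts the curve's linearity with BP null models.

library(hsmnet)

seed <- 20260929L
out <- "results"
units_info <- read_units("results/data/units.csv")

bp <- read_association(file.path(out, "association_bp_P1.csv"), "BP")
dend <- upgma(bp_distance(bp))
write_dendrogram(dend, file.path(out, "dendrogram_P1.nwk"))

curve <- bifurcation_curve(dend)
write.csv(curve, file.path(out, "bifurcation_curve_P1.csv"),
          row.names = FALSE)
knot <- detect_knot(curve)
message(sprintf("knot: d = %.4f (w = %.1f, p = %.4g)%s",
                knot$d_knot, knot$w, knot$p,
                if (knot$significant) "" else "  [not significant]"))

tier1 <- cut_tier1(dend, knot$d_knot, units_info)
write_partition(tier1, file.path(out, "tier1_partition_P1.csv"))
message(sprintf(
  "tier-1: %d clusters, mean %.2f units, mean %.1f individuals",
  tier1$n_clusters, tier1$mean_units, tier1$mean_individuals))

# linearity: the observed curve should fit a single gradient worse than
# BP null models do (their curves are near-linear by construction)
pm <- as.matrix(read.csv(file.path(out, "presence_P1.csv"), row.names = 1,
                         check.names = FALSE))
set.seed(seed)
ens <- null_ensemble(pm, "BP", n = 50)
null_r2 <- vapply(ens$matrices, function(m)
  linearity_r2(bifurcation_curve(upgma(bp_distance(m)))), numeric(1))
obs_r2 <- linearity_r2(curve)
message(sprintf("curve linearity R^2: observed %.3f vs null mean %.3f",
                obs_r2, mean(null_r2)))

jsonlite::write_json(
  list(knot = list(d = knot$d_knot, w = knot$w, p = knot$p,
                   significant = knot$significant),
       tier1 = list(n_clusters = tier1$n_clusters,
                    mean_units = tier1$mean_units,
                    mean_individuals = tier1$mean_individuals),
       linearity = list(observed_r2 = obs_r2,
                        null_mean_r2 = mean(null_r2), n_null = 50)),
  file.path(out, "hierarchy_P1.json"), auto_unbox = TRUE, digits = NA)
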