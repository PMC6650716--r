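#!/usr/bin/env Rscript

# Stage 5: tier-size scaling and kinship structure.
#
# Assembles the mean social-unit size at each detected level (individuals,
# groups/solitaries, tier-1 clusters, tier-2 modules), fits the log-linear
# scaling relationship whose exp(slope) is the scaling ratio between
# adjacent tiers, and tests whether silverback relatedness predicts tier-2
# module co-membership.

library(hsmnet)

out <- "results"
units_info <- read_units("results/data/units.csv")
kinship <- read_kinship("results/data/kinship.csv")

load_part <- function(path, tier) {
  df <- read.csv(path)
  hsmnet:::tier_partition(tier, setNames(df$cluster, df$unit_id), units_info)
}
tier1 <- load_part(file.path(out, "tier1_partition_P1.csv"), 1L)
tier2_sr <- load_part(file.path(out, "tier2_sr_P1.csv"), 2L)
tier2_bp <- load_part(file.path(out, "tier2_bp_P1.csv"), 2L)

tab <- suppressWarnings(tier_sizes(tier1, tier2_sr, units_info,
                                   population = "synthetic"))
write.csv(tab, file.path(out, "tier_sizes_P1.csv"), row.names = FALSE)
fit <- scaling_fit(tab)
message(sprintf("tier sizes (individuals): %s",
                paste(sprintf("L%d=%.2f", tab$level, tab$size),
                      collapse = ", ")))
message(sprintf("scaling ratio = %.2f (R^2 = %.3f, p = %.3g)",
                fit$ratio, fit$r_squared, fit$p))

kin_bp <- suppressWarnings(kinship_glm(kinship, tier2_bp, units_info))
kin_sr <- suppressWarnings(kinship_glm(kinship, tier2_sr, units_info))
for (x in list(c("BP", "kin_bp"), c("SR", "kin_sr"))) {
  k <- get(x[2])
  z <- if (k$separated) k$z_corrected else k$z
  message(sprintf(
    "kinship -> %s modules: z = %.2f%s; %.1f%% of same-module pairs related (%d pairs)",
    x[1], z, if (k$separated) " (corrected; separated)"
    else sprintf(", p = %.3g", k$p),
    100 * k$related_fraction, k$n_pairs))
}

jsonlite::write_json(
  list(scaling = list(ratio = fit$ratio, r_squared = fit$r_squared,
                      p = fit$p, n_points = fit$n_points),
       kinship_bp = kin_bp[c("z", "z_corrected", "p", "related_fraction",
                             "n_pairs", "separated")],
       kinship_sr = kin_sr[c("z", "z_corrected", "p", "related_fraction",
                             "n_pairs", "separated")]),
  file.path(out, "scaling_kinship_P1.json"), auto_unbox = TRUE, digits = NA)
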