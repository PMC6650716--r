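#!/usr/bin/env Rscript

# Stage 1: simulate the synthetic covisit study.
#
# Generates a population of 48 social units (27 groups, 21 solitary males)
# with two planted social tiers — clusters of ~2 units nested inside
# modules of ~8 units — and simulates two consecutive 730-day visit streams
# to a shared resource hotspot, with heterogeneous unit visit rates and a
# sinusoidal seasonal cycle. Writes the CSV fixture set the later stages
# consume, plus the ground truth for the recovery stage.

library(hsmnet)

seed <- 20260929L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config()
truth <- generate_population(cfg, seed = seed)
visits_a <- simulate_visits(truth, seed = seed + 1L)
visits_b <- simulate_visits(truth, seed = seed + 2L)   # second period,
visits_b$day <- visits_b$day + cfg$T_days              # same society

write_synthetic(truth, rbind(visits_a, visits_b), out)

message(sprintf(
  "simulated %d units (%d groups, %d solitaries) over 2 x %d days",
  cfg$n_units, sum(truth$units_info$kind == "group"),
  sum(truth$units_info$kind == "solitary"), cfg$T_days))
message(sprintf(
  "planted structure: %d tier-1 clusters (mean %.2f units) in %d tier-2 modules (mean %.2f units)",
  length(unique(truth$tier1_labels)), mean(table(truth$tier1_labels)),
  length(unique(truth$tier2_labels)), mean(table(truth$tier2_labels))))
message(sprintf("%d visit records written to %s",
                nrow(visits_a) + nrow(visits_b), out))
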