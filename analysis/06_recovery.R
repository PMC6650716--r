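#!/usr/bin/env Rscript

# Stage 6: recovery against the planted truth.
#
# Because the study is synthetic, every inferred structure can be scored
# against the generator's ground truth: Adjusted Rand Index of the tier-1
# and tier-2 partitions, knot detection, and the fitted scaling ratio
# against the multiplier implied by the planted tier sizes.

library(hsmnet)

out <- "results"
units_info <- read_units("results/data/units.csv")
truth_json <- jsonlite::read_json("results/data/truth.json")
truth <- list(
  tier1_labels = unlist(truth_json$tier1_labels),
  tier2_labels = unlist(truth_json$tier2_labels),
  units_info = units_info,
  cfg = truth_json$cfg
)
class(truth) <- "synthetic_truth"

load_part <- function(path, tier) {
  df <- read.csv(path)
  hsmnet:::tier_partition(tier, setNames(df$cluster, df$unit_id), units_info)
}
tier1 <- load_part(file.path(out, "tier1_partition_P1.csv"), 1L)
tier2 <- load_part(file.path(out, "tier2_sr_P1.csv"), 2L)
hier <- jsonlite::read_json(file.path(out, "hierarchy_P1.json"))
scaling <- jsonlite::read_json(file.path(out, "scaling_kinship_P1.json"))

true_tab <- true_tier_sizes(truth)
true_ratio <- scaling_fit(true_tab)$ratio

metrics <- list(
  tier1_ari = partition_ari(truth$tier1_labels, tier1),
  tier2_ari = partition_ari(truth$tier2_labels, tier2),
  knot_significant = hier$knot$significant,
  scaling_ratio_fitted = scaling$scaling$ratio,
  scaling_ratio_true = true_ratio,
  scaling_ratio_rel_error =
    abs(scaling$scaling$ratio - true_ratio) / true_ratio
)
message(sprintf("tier-1 ARI = %.3f, tier-2 ARI = %.3f",
                metrics$tier1_ari, metrics$tier2_ari))
message(sprintf("knot significant: %s", metrics$knot_significant))
message(sprintf(
  "scaling ratio: fitted %.2f vs planted %.2f (relative error %.1f%%)",
  metrics$scaling_ratio_fitted, metrics$scaling_ratio_true,
  100 * metrics$scaling_ratio_rel_error))

jsonlite::write_json(metrics, file.path(out, "recovery_P1.json"),
                     auto_unbox = TRUE, digits = NA)
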