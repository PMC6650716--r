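#' Configuration for the synthetic covisit generator
#'
#' Defaults emulate a multi-year record of gorilla units visiting a forest
#' clearing: 48 units (a little under half solitary males) observed over
#' two years, with planted first-tier clusters of about 2 units nested
#' inside second-tier modules of about 8 units, heterogeneous per-unit
#' visit rates, and a sinusoidal seasonal fluctuation in overall
#' visitation.
#'
#' Covisit correlation is induced by shared latent "excursion" events: each
#' day every cluster and every module independently draws an excursion,
#' and a unit's visit probability is multiplied by `within_tier1_boost`
#' when its cluster's excursion fires and by `within_tier2_boost` when its
#' module's does. This makes the nested structure literal and scales to
#' any module size.
#'
#' @param n_units Number of social units.
#' @param mean_tier1_size Mean units per first-tier cluster.
#' @param mean_tier2_size Mean units per second-tier module.
#' @param T_days Observation days.
#' @param base_visit_rate Baseline per-unit per-day visit probability.
#' @param within_tier1_boost,within_tier2_boost Multiplicative visit-rate
#'   factors on cluster/module excursion days (1 = no structure).
#' @param excursion_prob Per-day probability that a cluster (or module)
#'   draws a shared excursion.
#' @param seasonal_amplitude Amplitude of the sinusoidal annual cycle in
#'   [0, 1).
#' @param fraction_solitary Fraction of units that are solitary males
#'   (size 1).
#' @param group_size_mean Mean individuals per group unit (groups are
#'   2 + Poisson).
#' @param rate_shape Gamma shape of per-unit rate multipliers (mean 1);
#'   `Inf` gives homogeneous rates.
#' @param kin_prob_within_module,kin_prob_between Probability that a
#'   silverback pair is related (binary kinship) within vs between
#'   modules.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_units = 48L,
                             mean_tier1_size = 2,
                             mean_tier2_size = 8,
                             T_days = 730L,
                             base_visit_rate = 0.03,
                             within_tier1_boost = 10,
                             within_tier2_boost = 6,
                             excursion_prob = 0.3,
                             seasonal_amplitude = 0.3,
                             fraction_solitary = 21 / 48,
                             group_size_mean = 7,
                             rate_shape = 4,
                             kin_prob_within_module = 0.35,
                             kin_prob_between = 0.05) {
  cfg <- list(n_units = as.integer(n_units),
              mean_tier1_size = mean_tier1_size,
              mean_tier2_size = mean_tier2_size,
              T_days = as.integer(T_days),
              base_visit_rate = base_visit_rate,
              within_tier1_boost = within_tier1_boost,
              within_tier2_boost = within_tier2_boost,
              excursion_prob = excursion_prob,
              seasonal_amplitude = seasonal_amplitude,
              fraction_solitary = fraction_solitary,
              group_size_mean = group_size_mean,
              rate_shape = rate_shape,
              kin_prob_within_module = kin_prob_within_module,
              kin_prob_between = kin_prob_between)
  if (cfg$mean_tier1_size > cfg$mean_tier2_size)
    stop("mean_tier1_size cannot exceed mean_tier2_size (clusters nest in modules)")
  if (cfg$mean_tier1_size < 1 || cfg$mean_tier2_size < 1)
    stop("tier sizes must be >= 1")
  if (cfg$within_tier1_boost < 1 || cfg$within_tier2_boost < 1)
    stop("boosts must be >= 1")
  if (cfg$seasonal_amplitude < 0 || cfg$seasonal_amplitude >= 1)
    stop("seasonal_amplitude must be in [0, 1)")
  structure(cfg, class = "generator_config")
}

# Partition `ids` into blocks with sizes ~ 1 + Poisson(mean - 1). Used for
# first-tier clusters, where singletons (units that pair with nobody) are a
# natural part of the social structure.
random_blocks <- function(ids, mean_size) {
  n <- length(ids)
  sizes <- integer(0)
  while (sum(sizes) < n)
    sizes <- c(sizes, 1L + rpois(1L, max(mean_size - 1, 0)))
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
  sizes <- sizes[sizes > 0L]
  rep(seq_along(sizes), sizes)
}

# Partition `ids` into round(n / mean_size) blocks whose sizes scatter
# moderately around the mean (gamma-weight apportionment, every block at
# least half the mean). Used for second-tier modules: a "module of ~8
# units" should not degenerate to size 1-3, which the modularity criterion
# cannot resolve at unit resolution.
apportion_blocks <- function(ids, mean_size) {
  n <- length(ids)
  k <- max(1L, as.integer(round(n / mean_size)))
  if (k == 1L) return(rep(1L, n))
  w <- rgamma(k, shape = 20, rate = 20)
  raw <- n * w / sum(w)
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    top <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[top] <- sizes[top] + 1L
  }
  min_size <- max(2L, floor(mean_size / 2))
  while (any(sizes < min_size)) {
    i <- which.min(sizes); j <- which.max(sizes)
    sizes[i] <- sizes[i] + 1L; sizes[j] <- sizes[j] - 1L
  }
  rep(seq_along(sizes), sizes)
}

#' Draw a synthetic population with planted two-tier structure
#'
#' Units are partitioned into second-tier modules (sizes around
#' `mean_tier2_size`) and, within each module, into first-tier clusters
#' (sizes around `mean_tier1_size`), so clusters are nested in modules by
#' construction. Unit kinds, sizes, per-unit rate multipliers and binary
#' silverback kinship (more likely within modules) are drawn alongside.
#'
#' @param cfg A [generator_config()].
#' @param seed Optional RNG seed.
#' @return Object of class `synthetic_truth`: `units_info`,
#'   `tier1_labels`, `tier2_labels` (named by unit), `kinship`,
#'   `rate_mult`, `cfg`.
#' @export
generate_population <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_units
  ids <- sprintf("u%02d", seq_len(n))
  ord <- sample(ids)
  tier2 <- setNames(apportion_blocks(ord, cfg$mean_tier2_size), ord)
  tier1 <- setNames(integer(n), ord)
  next_cl <- 1L
  for (m in unique(tier2)) {
    members <- names(tier2)[tier2 == m]
    cl <- random_blocks(members, cfg$mean_tier1_size)
    tier1[members] <- cl + next_cl - 1L
    next_cl <- next_cl + max(cl)
  }
  tier1 <- tier1[ids]; tier2 <- tier2[ids]
  solitary <- seq_len(n) %in% sample.int(n, round(cfg$fraction_solitary * n))
  sizes <- ifelse(solitary, 1L,
                  2L + rpois(n, max(cfg$group_size_mean - 2, 0)))
  units_info <- data.frame(
    unit_id = ids,
    kind = ifelse(solitary, "solitary", "group"),
    n_individuals = as.integer(sizes),
    silverback_id = sprintf("sb_%s", ids),
    stringsAsFactors = FALSE
  )
  rate_mult <- if (is.finite(cfg$rate_shape)) {
    setNames(rgamma(n, shape = cfg$rate_shape, rate = cfg$rate_shape), ids)
  } else {
    setNames(rep(1, n), ids)
  }
  pairs <- combn(units_info$silverback_id, 2L)
  same_mod <- tier2[sub("^sb_", "", pairs[1, ])] ==
    tier2[sub("^sb_", "", pairs[2, ])]
  kinship <- data.frame(
    silverback_a = pairs[1, ], silverback_b = pairs[2, ],
    related = rbinom(ncol(pairs), 1L,
                     ifelse(same_mod, cfg$kin_prob_within_module,
                            cfg$kin_prob_between)),
    stringsAsFactors = FALSE
  )
  structure(
    list(units_info = units_info, tier1_labels = tier1,
         tier2_labels = tier2, kinship = kinship,
         rate_mult = rate_mult, cfg = cfg),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic population: %d units, %d tier-1 clusters in %d tier-2 modules\n",
    length(x$tier1_labels), length(unique(x$tier1_labels)),
    length(unique(x$tier2_labels))))
  invisible(x)
}

#' Simulate a visit stream from a synthetic population
#'
#' Day `t` carries a seasonal factor
#' `s_t = 1 + seasonal_amplitude * sin(2*pi*t/365)`. Each cluster and each
#' module independently fires an excursion with probability
#' `excursion_prob` per day; unit `i` then visits with probability
#' `min(1, base_visit_rate * mult_i * s_t * b1^[cluster fired] *
#' b2^[module fired])`. Probabilities pushed past 1 are clamped with a
#' message.
#'
#' @param truth A `synthetic_truth` from [generate_population()].
#' @param seed Optional RNG seed.
#' @return Visit record data frame (`unit_id`, `day` 0-based), one row per
#'   unit-day visit.
#' @export
simulate_visits <- function(truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- truth$cfg
  n <- cfg$n_units
  Tn <- cfg$T_days
  ids <- truth$units_info$unit_id
  days <- seq_len(Tn) - 1L
  s_t <- 1 + cfg$seasonal_amplitude * sin(2 * pi * days / 365)
  cl <- truth$tier1_labels[ids]
  mo <- truth$tier2_labels[ids]
  cl_levels <- sort(unique(cl)); mo_levels <- sort(unique(mo))
  e1 <- matrix(rbinom(length(cl_levels) * Tn, 1L, cfg$excursion_prob),
               length(cl_levels), Tn)
  e2 <- matrix(rbinom(length(mo_levels) * Tn, 1L, cfg$excursion_prob),
               length(mo_levels), Tn)
  boost <- cfg$within_tier1_boost^e1[match(cl, cl_levels), , drop = FALSE] *
    cfg$within_tier2_boost^e2[match(mo, mo_levels), , drop = FALSE]
  p <- (cfg$base_visit_rate * truth$rate_mult[ids]) *
    boost * rep(s_t, each = n)
  over <- p > 1
  if (any(over)) {
    message(sprintf("clamped %d visit probabilities above 1", sum(over)))
    p[over] <- 1
  }
  hit <- matrix(rbinom(n * Tn, 1L, p), n, Tn)
  idx <- which(hit == 1L, arr.ind = TRUE)
  out <- data.frame(unit_id = ids[idx[, 1]], day = days[idx[, 2]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$day, out$unit_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the synthetic fixture set to a directory
#'
#' Emits the same `visits.csv`, `units.csv` and `kinship.csv` the pipeline
#' consumes, plus the ground truth as `truth.json`.
#'
#' @param truth A `synthetic_truth`.
#' @param visits Visit records from [simulate_visits()].
#' @param dir Output directory.
#' @export
write_synthetic <- function(truth, visits, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_visits(visits, file.path(dir, "visits.csv"))
  write.csv(truth$units_info, file.path(dir, "units.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(truth$kinship, file.path(dir, "kinship.csv"),
            row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(tier1_labels = as.list(truth$tier1_labels),
         tier2_labels = as.list(truth$tier2_labels),
         rate_mult = as.list(truth$rate_mult),
         cfg = unclass(truth$cfg)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between partitions over their shared units
#' (1 = identical up to relabeling, ~0 = independent).
#'
#' @param a,b Named cluster-label vectors or `tier_partition` objects.
#' @return ARI scalar.
#' @export
partition_ari <- function(a, b) {
  la <- if (inherits(a, "tier_partition")) a$assignment else a
  lb <- if (inherits(b, "tier_partition")) b$assignment else b
  shared <- intersect(names(la), names(lb))
  mclust::adjustedRandIndex(la[shared], lb[shared])
}

#' Recovery metrics against planted truth
#'
#' Scores a pipeline run on synthetic data: Adjusted Rand Index of the
#' recovered tier-1 and tier-2 partitions against the planted labels,
#' whether the knot scan found a significant tier transition, and the
#' relative error of the fitted scaling ratio against the multiplier
#' implied by the planted tier sizes.
#'
#' @param truth A `synthetic_truth`.
#' @param tier1,tier2 Recovered `tier_partition`s (either may be NULL).
#' @param knot Optional `knot_result`.
#' @param scaling Optional `scaling_fit`.
#' @return List of metrics.
#' @export
recovery_report <- function(truth, tier1 = NULL, tier2 = NULL,
                            knot = NULL, scaling = NULL) {
  out <- list()
  if (!is.null(tier1))
    out$tier1_ari <- partition_ari(truth$tier1_labels, tier1)
  if (!is.null(tier2))
    out$tier2_ari <- partition_ari(truth$tier2_labels, tier2)
  if (!is.null(knot)) {
    out$knot_significant <- knot$significant
    out$d_knot <- knot$d_knot
  }
  if (!is.null(scaling)) {
    true_tab <- true_tier_sizes(truth)
    true_ratio <- scaling_fit(true_tab)$ratio
    out$true_scaling_ratio <- true_ratio
    out$scaling_ratio <- scaling$ratio
    out$scaling_ratio_rel_error <- abs(scaling$ratio - true_ratio) / true_ratio
  }
  out
}

#' Tier-size table implied by the planted truth
#'
#' @param truth A `synthetic_truth`.
#' @return Data frame as from [tier_sizes()] (levels 1, 3, 4, 5).
#' @export
true_tier_sizes <- function(truth) {
  t1 <- tier_partition(1L, truth$tier1_labels, truth$units_info)
  t2 <- tier_partition(2L, truth$tier2_labels, truth$units_info)
  suppressWarnings(
    tier_sizes(t1, t2, truth$units_info, population = "truth"))
}
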