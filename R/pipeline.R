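#' Configuration for an end-to-end pipeline run
#'
#' Bundles the input paths, filtering and null-model settings used by
#' [run_pipeline()]. Defaults follow the conventions of the covisit
#' analysis this package implements: units seen fewer than 8 times in a
#' period are dropped, 1000 permutations per null ensemble, resolutions 0
#' to 2 in steps of 0.01, significance at 0.05.
#'
#' @param visits_path,units_path Paths to the visits and units CSVs.
#' @param kinship_path Optional kinship CSV path.
#' @param periods Optional list of `study_period`s; `NULL` analyses the
#'   whole record as one period.
#' @param min_visits Minimum visits to retain a unit (default 8).
#' @param n_perm Null-ensemble size (default 1000).
#' @param swaps_per_sample Thinning interval of the data-stream chain.
#' @param gammas Resolution grid for the sweep.
#' @param run_sweep Run the resolution sweep? (It dominates runtime.)
#' @param rate_adjust Use the attendance-adjusted BP index?
#' @param alpha Significance threshold.
#' @param restarts Louvain restarts for headline modularity.
#' @param sweep_restarts Louvain restarts inside the sweep.
#' @param seed RNG seed for the whole run.
#' @param out_dir Output directory.
#' @param extra_levels Sizes for social levels 2, 6, 7 (see
#'   [tier_sizes()]).
#' @return A `run_config` list.
#' @export
run_config <- function(visits_path, units_path, kinship_path = NULL,
                       periods = NULL, min_visits = 8L, n_perm = 1000L,
                       swaps_per_sample = 500L,
                       gammas = seq(0, 2, by = 0.01), run_sweep = TRUE,
                       rate_adjust = FALSE, alpha = 0.05, restarts = 10L,
                       sweep_restarts = 3L, seed = 1L, out_dir = "results",
                       extra_levels = c()) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full inference chain on one dataset
#'
#' For each study period: build and filter the presence matrix, compute SR
#' and BP association matrices, generate null ensembles, cluster the BP
#' distances by UPGMA and detect the tier-1 knot, run Louvain with
#' permutation p-values for both indices, optionally sweep the resolution
#' parameter (SR only) and locate p-value troughs, regress tier-2
#' co-membership on tier-1 co-membership, fit the tier-size scaling ratio,
#' and (when kinship data are supplied) regress module co-membership on
#' silverback relatedness. Consecutive periods are compared with Mantel
#' tests on the SR matrices. All stage outputs are written under
#' `cfg$out_dir` and a JSON summary is returned invisibly.
#'
#' @param cfg A [run_config()].
#' @return The summary list (also written as `summary.json`), invisibly.
#' @export
run_pipeline <- function(cfg) {
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  visits <- read_visits(cfg$visits_path)
  units_info <- read_units(cfg$units_path)
  kinship <- if (!is.null(cfg$kinship_path)) read_kinship(cfg$kinship_path)
  periods <- cfg$periods
  if (is.null(periods))
    periods <- list(study_period("all", min(visits$day), max(visits$day)))
  split <- split_periods(visits, periods)

  summary <- list(config = list(
    min_visits = cfg$min_visits, n_perm = cfg$n_perm,
    swaps_per_sample = cfg$swaps_per_sample, alpha = cfg$alpha,
    rate_adjust = cfg$rate_adjust, restarts = cfg$restarts,
    seed = cfg$seed,
    gammas = if (cfg$run_sweep) range(cfg$gammas) else NULL),
    periods = list())
  sr_by_period <- list()

  for (lab in names(split)) {
    pd <- split[[lab]]
    pdir <- file.path(cfg$out_dir, lab)
    dir.create(pdir, showWarnings = FALSE)
    pm <- filter_min_visits(pd$presence, cfg$min_visits)
    write_presence(pm, file.path(pdir, "presence.csv"))

    sr <- simple_ratio(pm)
    bp <- binomial_probability(pm, rate_adjust = cfg$rate_adjust)
    write_association(sr, file.path(pdir, "association_sr.csv"))
    write_association(bp, file.path(pdir, "association_bp.csv"))
    sr_by_period[[lab]] <- sr

    ens_sr <- null_ensemble(pm, "SR", n = cfg$n_perm,
                            swaps_per_sample = cfg$swaps_per_sample)
    ens_bp <- null_ensemble(pm, "BP", n = cfg$n_perm,
                            rate_adjust = cfg$rate_adjust)

    dend <- upgma(bp_distance(bp))
    write_dendrogram(dend, file.path(pdir, "dendrogram.nwk"))
    curve <- bifurcation_curve(dend)
    write.csv(curve, file.path(pdir, "bifurcation_curve.csv"),
              row.names = FALSE)
    knot <- tryCatch(detect_knot(curve, alpha = cfg$alpha),
                     error = function(e) NULL)
    tier1 <- if (!is.null(knot))
      cut_tier1(dend, knot$d_knot, units_info) else NULL
    if (!is.null(tier1))
      write_partition(tier1, file.path(pdir, "tier1_partition.csv"))

    mod_sr <- modularity_p(sr, ens_sr, restarts = cfg$restarts,
                           units_info = units_info)
    mod_bp <- modularity_p(bp, ens_bp, restarts = cfg$restarts,
                           units_info = units_info)
    write_partition(mod_sr$partition, file.path(pdir, "tier2_sr.csv"))
    write_partition(mod_bp$partition, file.path(pdir, "tier2_bp.csv"))

    sweep <- troughs <- NULL
    if (cfg$run_sweep) {
      sweep <- resolution_sweep(sr, ens_sr, gammas = cfg$gammas,
                                restarts = cfg$sweep_restarts,
                                units_info = units_info)
      write.csv(sweep, file.path(pdir, "resolution_sweep.csv"),
                row.names = FALSE)
      troughs <- find_troughs(sweep, alpha = cfg$alpha)
      write.csv(troughs, file.path(pdir, "sweep_troughs.csv"),
                row.names = FALSE)
    }

    consistency <- if (!is.null(tier1))
      comembership_glm(tier1, mod_sr$partition) else NULL

    scaling <- NULL
    if (!is.null(tier1)) {
      tab <- suppressWarnings(
        tier_sizes(tier1, mod_sr$partition, units_info,
                   extra_levels = cfg$extra_levels, population = lab))
      scaling <- scaling_fit(tab)
      write.csv(tab, file.path(pdir, "tier_sizes.csv"), row.names = FALSE)
    }

    kin <- if (!is.null(kinship))
      tryCatch(kinship_glm(kinship, mod_bp$partition, units_info),
               error = function(e) NULL)

    summary$periods[[lab]] <- list(
      n_units = nrow(pm), n_days = ncol(pm),
      knot = if (!is.null(knot))
        list(d = knot$d_knot, w = knot$w, p = knot$p,
             significant = knot$significant),
      tier1 = if (!is.null(tier1))
        list(n_clusters = tier1$n_clusters, mean_units = tier1$mean_units,
             mean_individuals = tier1$mean_individuals),
      modularity = list(
        SR = list(Q = mod_sr$Q, p = mod_sr$p,
                  n_modules = mod_sr$partition$n_clusters,
                  mean_units = mod_sr$partition$mean_units,
                  mean_individuals = mod_sr$partition$mean_individuals),
        BP = list(Q = mod_bp$Q, p = mod_bp$p,
                  n_modules = mod_bp$partition$n_clusters)),
      troughs = if (!is.null(troughs) && nrow(troughs) > 0)
        lapply(seq_len(nrow(troughs)), function(i) as.list(troughs[i, ])),
      consistency = if (!is.null(consistency))
        consistency[c("z", "p", "separated")],
      scaling = if (!is.null(scaling))
        scaling[c("ratio", "r_squared", "p", "n_points")],
      kinship = if (!is.null(kin))
        kin[c("z", "p", "related_fraction", "n_pairs", "separated")]
    )
  }

  if (length(sr_by_period) > 1L) {
    labs <- names(sr_by_period)
    mant <- list()
    for (i in seq_len(length(labs) - 1L)) {
      for (j in (i + 1L):length(labs)) {
        mr <- tryCatch(
          mantel_association(sr_by_period[[i]], sr_by_period[[j]],
                             n_perm = cfg$n_perm),
          error = function(e) NULL)
        if (!is.null(mr))
          mant[[paste(labs[i], labs[j], sep = "_vs_")]] <-
            list(Z = mr$Z, p = mr$p, n_units = mr$n_units)
      }
    }
    summary$mantel <- mant
  }

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(summary)
}
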