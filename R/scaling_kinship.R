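#' Mean social-unit size at each social level
#'
#' Assembles the tier-size table used for the scaling analysis. Levels
#' follow the standard multi-level classification: 1 = individuals
#' (size 1 by definition), 2 = mother-offspring units, 3 = groups and
#' solitaries, 4 = first-tier associations (clusters of units),
#' 5 = second-tier associations (modules), 6 = sub-population,
#' 7 = population. Levels 3-5 are computed from the data (individual
#' counts, weighted by unit sizes); levels 2, 6 and 7 cannot be derived
#' from a covisit stream and must be supplied via `extra_levels` or they
#' are omitted with a warning.
#'
#' @param tier1,tier2 `tier_partition` objects with `mean_individuals`
#'   available.
#' @param units_info Unit metadata with `n_individuals`.
#' @param extra_levels Named numeric vector giving sizes for levels `"2"`,
#'   `"6"`, `"7"` (any subset).
#' @param population Population label attached to the table.
#' @return Data frame with columns `population`, `level`, `size`.
#' @export
tier_sizes <- function(tier1, tier2, units_info,
                       extra_levels = c(), population = "synthetic") {
  sizes <- c("1" = 1,
             "3" = mean(units_info$n_individuals),
             "4" = tier1$mean_individuals,
             "5" = tier2$mean_individuals)
  for (lv in c("2", "6", "7")) {
    if (lv %in% names(extra_levels)) {
      sizes[lv] <- extra_levels[[lv]]
    } else {
      warning(sprintf("no size supplied for social level %s; point omitted",
                      lv))
    }
  }
  sizes <- sizes[!is.na(sizes)]
  out <- data.frame(population = population,
                    level = as.integer(names(sizes)),
                    size = unname(sizes))
  out[order(out$level), ]
}

#' Fit the scaling ratio of social-unit sizes across levels
#'
#' Ordinary least squares of `log(size)` on social level. If group size at
#' each tier is a constant multiple of the tier below, the relationship is
#' exactly log-linear and `exp(slope)` recovers that multiplier (the
#' scaling ratio). With several populations, `combine = "pool"` fits all
#' points with population intercepts; `combine = "mean"` first averages
#' sizes at each level across populations and fits the means (the default
#' for a combined ratio).
#'
#' @param table Data frame from [tier_sizes()] (rows from several
#'   populations may be concatenated).
#' @param combine `"pool"` or `"mean"`; only relevant with more than one
#'   population.
#' @return Object of class `scaling_fit`: `ratio` (= exp(slope)),
#'   `r_squared`, `p` (two-sided, slope), `n_points`.
#' @export
scaling_fit <- function(table, combine = c("mean", "pool")) {
  combine <- match.arg(combine)
  if (any(table$size <= 0)) stop("social unit sizes must be positive")
  multi <- length(unique(table$population)) > 1L
  if (multi && combine == "mean") {
    agg <- aggregate(size ~ level, data = table, FUN = mean)
    fit <- lm(log(size) ~ level, data = agg)
    n <- nrow(agg)
  } else if (multi) {
    fit <- lm(log(size) ~ level + factor(population), data = table)
    n <- nrow(table)
  } else {
    if (nrow(table) < 3L) stop("need at least 3 levels for a scaling fit")
    fit <- lm(log(size) ~ level, data = table)
    n <- nrow(table)
  }
  s <- summary(fit)
  structure(
    list(ratio = exp(unname(coef(fit)["level"])),
         r_squared = s$r.squared,
         p = unname(s$coefficients["level", "Pr(>|t|)"]),
         n_points = n, combine = if (multi) combine else "single"),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("scaling ratio = %.2f (R^2 = %.3f, p = %.3g, %d points)\n",
              x$ratio, x$r_squared, x$p, x$n_points))
  invisible(x)
}

#' Kinship prediction of module co-membership
#'
#' Logistic regression, over silverback pairs with known binary kinship, of
#' module co-membership (the two silverbacks' units in the same tier-2
#' module) on relatedness (1 = half-siblings or closer). Also reports the
#' fraction of same-module pairs with known kinship that are related. As
#' with [comembership_glm()], dyads are not independent and the Wald z is
#' a descriptive statistic.
#'
#' @param kinship Data frame with `silverback_a`, `silverback_b`,
#'   `related`.
#' @param partition A `tier_partition` (tier-2 modules).
#' @param units_info Unit metadata linking `silverback_id` to `unit_id`.
#' @return Object of class `kinship_result`: `z`, `p`, `related_fraction`,
#'   `n_pairs`, `separated`.
#' @export
kinship_glm <- function(kinship, partition, units_info) {
  sb2unit <- setNames(units_info$unit_id, units_info$silverback_id)
  ua <- sb2unit[kinship$silverback_a]
  ub <- sb2unit[kinship$silverback_b]
  known <- !is.na(ua) & !is.na(ub) &
    ua %in% names(partition$assignment) &
    ub %in% names(partition$assignment)
  if (sum(known) < 3L)
    stop("need at least 3 kinship pairs mapping to partitioned units")
  same <- as.integer(partition$assignment[ua[known]] ==
                       partition$assignment[ub[known]])
  related <- as.integer(kinship$related[known])
  if (sum(same) == 0L)
    stop("no same-module pairs with known kinship")
  related_fraction <- mean(related[same == 1L])
  tab <- table(factor(related, levels = 0:1), factor(same, levels = 0:1))
  if (any(tab == 0L)) {
    warning("complete separation in kinship regression")
    return(structure(
      list(z = NA_real_, p = NA_real_, related_fraction = related_fraction,
           n_pairs = sum(known), separated = TRUE, table = tab,
           z_corrected = haldane_z(tab)),
      class = "kinship_result"))
  }
  fit <- glm(same ~ related, family = binomial())
  s <- summary(fit)$coefficients["related", ]
  structure(
    list(z = unname(s["z value"]), p = unname(s["Pr(>|z|)"]),
         related_fraction = related_fraction, n_pairs = sum(known),
         separated = FALSE, table = tab, z_corrected = haldane_z(tab)),
    class = "kinship_result"
  )
}

#' @export
print.kinship_result <- function(x, ...) {
  if (x$separated) {
    cat("kinship regression: complete separation (infinite slope)\n")
  } else {
    cat(sprintf(
      "kinship regression: z = %.2f, p = %.3g; %.1f%% of same-module pairs related (%d pairs)\n",
      x$z, x$p, 100 * x$related_fraction, x$n_pairs))
  }
  invisible(x)
}
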