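#' Transform BP tail probabilities into clustering distances
#'
#' Distance between two units is their binomial-probability upper-tail
#' raised to the power 2/3: `d_ij = p_ij^(2/3)`. Small tail (covisiting far
#' beyond chance) means small distance. The 2/3 power is chosen so that the
#' cumulative-bifurcation curve of dendrograms built from *null* data is
#' approximately linear in distance, making a change of gradient in real
#' data interpretable as a transition between social tiers.
#'
#' @param A An `assoc_matrix` with `index_type = "BP"`.
#' @return Symmetric distance matrix in [0, 1] with zero diagonal.
#' @export
bp_distance <- function(A) {
  if (!inherits(A, "assoc_matrix") || A$index_type != "BP" || is.null(A$tail))
    stop("bp_distance() requires a BP association matrix with tail probabilities")
  d <- A$tail^(2 / 3)
  diag(d) <- 0
  d
}

#' UPGMA dendrogram of a distance matrix
#'
#' Average-linkage (UPGMA) agglomerative clustering; merge heights are the
#' average inter-cluster distance at fusion, giving an ultrametric tree.
#'
#' @param D Symmetric distance matrix with unit labels.
#' @return An [stats::hclust] tree.
#' @export
upgma <- function(D) {
  if (nrow(as.matrix(D)) < 2L) stop("need at least 2 leaves")
  if (any(is.na(D))) stop("distance matrix contains NA")
  hclust(as.dist(D), method = "average")
}

#' Export a dendrogram as Newick
#'
#' @param dend An `hclust` tree.
#' @param path Output path.
#' @export
write_dendrogram <- function(dend, path) {
  ape::write.tree(ape::as.phylo(dend), file = path)
  invisible(path)
}

#' Cumulative bifurcation curve of a dendrogram
#'
#' The merge heights in ascending order against the cumulative number of
#' joins (1 .. n-1). Reading the dendrogram from tips to root, this curve
#' records how fast bifurcations accumulate with association distance; a
#' gradient change marks the boundary between social tiers.
#'
#' @param dend An `hclust` tree.
#' @return Data frame with columns `height` and `cumulative`.
#' @export
bifurcation_curve <- function(dend) {
  h <- sort(dend$height)
  data.frame(height = h, cumulative = seq_along(h))
}

#' R-squared of the linear fit to a bifurcation curve
#'
#' Null-model dendrograms produce nearly linear curves (by construction of
#' the distance transform), so the linear R-squared separates structured
#' from random networks: real multi-tier data fit a single gradient worse.
#'
#' @param curve Data frame from [bifurcation_curve()].
#' @return R-squared of OLS `cumulative ~ height`.
#' @export
linearity_r2 <- function(curve) {
  if (nrow(curve) < 3L) stop("need at least 3 curve points")
  if (sd(curve$height) == 0) stop("constant heights: linear fit undefined")
  summary(lm(cumulative ~ height, data = curve))$r.squared
}

#' Detect a tier-transition knot in a bifurcation curve
#'
#' Computes local gradients of the cumulative-bifurcation curve between
#' consecutive distinct heights (ties share one step), then scans every
#' split point with at least `min_side` gradients on each side, comparing
#' the gradient distributions below and above by a two-sample Wilcoxon
#' rank-sum test. The knot is the split with the smallest p-value; it is
#' significant when p < `alpha`. Within a tier joins accumulate at a roughly
#' constant rate, so a significant gradient change marks the distance at
#' which one social tier gives way to the next.
#'
#' The test is exact when both sides have at most 25 gradients and no ties,
#' and uses the normal approximation with tie correction otherwise.
#'
#' @param curve Data frame from [bifurcation_curve()].
#' @param min_side Minimum gradients on each side of a candidate split.
#' @param alpha Significance threshold.
#' @return Object of class `knot_result`: `d_knot` (height at the gradient
#'   change), `w` (rank-sum statistic of the below-knot gradients), `p`,
#'   `significant`, and the gradient series.
#' @export
detect_knot <- function(curve, min_side = 5L, alpha = 0.05) {
  agg <- aggregate(cumulative ~ height, data = curve, FUN = max)
  agg <- agg[order(agg$height), ]
  hs <- agg$height
  cum <- agg$cumulative
  if (length(hs) < 2L) stop("all merges at one height: no gradients")
  g <- diff(cum) / diff(hs)
  K <- length(g)
  if (K < 2L * min_side)
    stop(sprintf("need at least %d gradients for a knot scan, have %d",
                 2L * min_side, K))
  best <- list(p = Inf)
  for (j in min_side:(K - min_side)) {
    below <- g[1:j]
    above <- g[(j + 1L):K]
    exact <- max(length(below), length(above)) <= 25L &&
      !any(duplicated(c(below, above)))
    wt <- suppressWarnings(
      wilcox.test(below, above, exact = exact, correct = TRUE))
    if (wt$p.value < best$p) {
      # rank-sum of the below sample = Mann-Whitney U + n_b(n_b+1)/2
      w_ranksum <- unname(wt$statistic) + length(below) * (length(below) + 1) / 2
      best <- list(j = j, p = wt$p.value, w = w_ranksum)
    }
  }
  structure(
    list(d_knot = hs[best$j + 1L], w = best$w, p = best$p,
         significant = best$p < alpha, alpha = alpha,
         gradients = g, heights = hs),
    class = "knot_result"
  )
}

#' @export
print.knot_result <- function(x, ...) {
  cat(sprintf("knot at d = %.3f (w = %.1f, p = %.4f)%s\n",
              x$d_knot, x$w, x$p,
              if (x$significant) "" else " [not significant]"))
  invisible(x)
}

#' Tier partition constructor (internal)
#' @keywords internal
tier_partition <- function(tier, assignment, units_info = NULL) {
  mean_units <- mean(table(assignment))
  mean_individuals <- NA_real_
  if (!is.null(units_info)) {
    sizes <- units_info$n_individuals[match(names(assignment),
                                            units_info$unit_id)]
    if (any(is.na(sizes))) {
      warning("unit sizes missing for some units; mean_individuals omitted")
    } else {
      mean_individuals <- mean(tapply(sizes, assignment, sum))
    }
  }
  structure(
    list(tier = as.integer(tier), assignment = assignment,
         n_clusters = length(unique(assignment)),
         mean_units = mean_units, mean_individuals = mean_individuals),
    class = "tier_partition"
  )
}

#' @export
print.tier_partition <- function(x, ...) {
  cat(sprintf(
    "tier-%d partition: %d clusters over %d units (mean %.2f units%s)\n",
    x$tier, x$n_clusters, length(x$assignment), x$mean_units,
    if (is.na(x$mean_individuals)) ""
    else sprintf(", %.1f individuals", x$mean_individuals)))
  invisible(x)
}

#' Cut the dendrogram below the knot into tier-1 clusters
#'
#' Units whose subtree merges entirely below `d_knot` form one first-tier
#' cluster; units that only join the tree at or above the knot are
#' singletons. Equivalent to thresholding the cophenetic distance strictly
#' below `d_knot`.
#'
#' @param dend An `hclust` tree.
#' @param d_knot Knot height from [detect_knot()].
#' @param units_info Optional unit metadata for individual-weighted sizes.
#' @return A `tier_partition` with `tier = 1`.
#' @export
cut_tier1 <- function(dend, d_knot, units_info = NULL) {
  h <- dend$height
  below <- h[h < d_knot]
  cl <- if (length(below) == 0L) {
    setNames(seq_along(dend$labels), dend$labels)
  } else {
    cutree(dend, h = max(below))
  }
  tier_partition(1L, cl, units_info)
}

#' Write a tier partition to CSV
#'
#' @param part A `tier_partition`.
#' @param path Output path.
#' @export
write_partition <- function(part, path) {
  write.csv(data.frame(unit_id = names(part$assignment),
                       cluster = unname(part$assignment)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
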