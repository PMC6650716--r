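#' Build a weighted igraph from an association matrix (internal)
#' @keywords internal
assoc_graph <- function(A) {
  m <- if (inherits(A, "assoc_matrix")) A$values else A
  if (any(m < 0)) stop("association weights must be non-negative")
  if (all(m[upper.tri(m)] == 0)) stop("all association weights are zero")
  igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Modularity of a given partition at resolution gamma (internal)
#'
#' `Q(gamma) = sum_c [w_c/W - gamma * (s_c/(2W))^2]` with `w_c` the
#' intra-module weight, `s_c` the module strength and `W` the total weight.
#' @keywords internal
partition_modularity <- function(A, membership, gamma = 1) {
  g <- assoc_graph(A)
  igraph::modularity(g, membership, weights = igraph::E(g)$weight,
                     resolution = gamma)
}

#' Greedy single-node refinement of a partition (internal)
#'
#' Repeatedly moves single nodes to the community (including an empty one)
#' that most increases modularity at resolution gamma, until no move helps.
#' This is the Louvain local-moving phase applied to the final partition:
#' multi-level aggregation can lock nodes into choices that a later single
#' move would improve, and this pass removes exactly those.
#' @keywords internal
refine_partition <- function(m, memb, gamma) {
  n <- nrow(m)
  s <- rowSums(m)
  W <- sum(s) / 2
  memb <- match(memb, sort(unique(memb)))
  k <- max(memb) + 1L                   # one spare empty community
  C <- matrix(0, n, k)
  C[cbind(seq_len(n), memb)] <- 1
  M <- m %*% C                          # node-to-community weights
  s_c <- as.vector(crossprod(C, s))
  cnt <- tabulate(memb, nbins = k)
  repeat {
    improved <- FALSE
    for (i in seq_len(n)) {
      c1 <- memb[i]
      gain <- (M[i, ] - M[i, c1]) / W -
        gamma * s[i] * (s_c - (s_c[c1] - s[i])) / (2 * W^2)
      gain[c1] <- 0
      c2 <- which.max(gain)
      if (gain[c2] > 1e-12) {
        memb[i] <- c2
        s_c[c1] <- s_c[c1] - s[i]; s_c[c2] <- s_c[c2] + s[i]
        cnt[c1] <- cnt[c1] - 1L; cnt[c2] <- cnt[c2] + 1L
        M[, c1] <- M[, c1] - m[, i]; M[, c2] <- M[, c2] + m[, i]
        if (all(cnt > 0L)) {            # replenish the spare community
          M <- cbind(M, 0); s_c <- c(s_c, 0); cnt <- c(cnt, 0L)
        }
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  match(memb, sort(unique(memb)))
}

#' Louvain community detection on a weighted association network
#'
#' Greedy multi-level optimisation of weighted modularity at resolution
#' `gamma`, followed by a single-node local-move refinement until no move
#' improves Q (multi-level aggregation can freeze assignments that a later
#' single move would fix). Louvain output depends on the order nodes are
#' visited, so the optimisation is restarted `restarts` times with randomly
#' permuted node orders and the highest-modularity partition kept; given a
#' seed the result is deterministic.
#'
#' @param A An `assoc_matrix` (or labeled non-negative matrix).
#' @param gamma Resolution parameter: larger values favour smaller modules.
#' @param seed Optional RNG seed.
#' @param restarts Node-order restarts (default 10).
#' @param units_info Optional unit metadata for individual-weighted module
#'   sizes.
#' @return Object of class `modularity_result`: `partition` (a
#'   `tier_partition`, tier 2), `Q`, `gamma`, and `p` (NA until compared to
#'   a null ensemble).
#' @export
louvain <- function(A, gamma = 1, seed = NULL, restarts = 10L,
                    units_info = NULL) {
  m <- if (inherits(A, "assoc_matrix")) A$values else A
  if (nrow(m) < 2L) stop("need at least 2 units")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(m)
  best_q <- -Inf
  best_memb <- NULL
  for (r in seq_len(restarts)) {
    ord <- if (r == 1L) seq_len(n) else sample.int(n)
    mo <- m[ord, ord, drop = FALSE]
    g <- assoc_graph(mo)
    memb <- refine_partition(mo, as.integer(igraph::membership(
      igraph::cluster_louvain(g, resolution = gamma))), gamma)
    q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight,
                            resolution = gamma)
    if (q > best_q) {
      best_q <- q
      best_memb <- setNames(integer(n), rownames(m))
      best_memb[ord] <- as.integer(memb)
    }
  }
  structure(
    list(partition = tier_partition(2L, best_memb, units_info),
         Q = best_q, gamma = gamma, p = NA_real_),
    class = "modularity_result"
  )
}

#' @export
print.modularity_result <- function(x, ...) {
  cat(sprintf("Louvain at gamma = %.2f: Q = %.3f (%d modules%s)\n",
              x$gamma, x$Q, x$partition$n_clusters,
              if (is.na(x$p)) "" else sprintf(", p = %.4g", x$p)))
  invisible(x)
}

#' Modularity with an empirical permutation p-value
#'
#' Optimises modularity on the observed association matrix and on every
#' matrix of a null ensemble at the same resolution and the same number of
#' restarts, and reports the add-one empirical p-value for the observed Q
#' exceeding the null distribution.
#'
#' @param A An `assoc_matrix`.
#' @param ensemble A `null_ensemble` of matching index type.
#' @param gamma Resolution parameter.
#' @param seed Optional RNG seed.
#' @param restarts Node-order restarts applied to observed and null
#'   optimisations alike.
#' @param units_info Optional unit metadata.
#' @return A `modularity_result` with `p` filled in and the null modularity
#'   values attached as `null_Q`.
#' @export
modularity_p <- function(A, ensemble, gamma = 1, seed = NULL,
                         restarts = 10L, units_info = NULL) {
  if (ensemble$n < 1L) stop("empty null ensemble")
  if (inherits(A, "assoc_matrix") &&
      ensemble$index_type != A$index_type)
    stop("ensemble index type does not match the association matrix")
  if (!is.null(seed)) set.seed(seed)
  obs <- louvain(A, gamma = gamma, restarts = restarts,
                 units_info = units_info)
  null_q <- vapply(ensemble$matrices, function(nm) {
    louvain(nm, gamma = gamma, restarts = restarts)$Q
  }, numeric(1))
  obs$p <- empirical_p(obs$Q, null_q, "ge")
  obs$null_Q <- null_q
  obs
}

#' Sweep the modularity resolution parameter
#'
#' Runs Louvain at every resolution in `gammas` on the observed matrix and
#' on each null-ensemble matrix, recording modularity, its empirical
#' p-value, and module counts/sizes. A single-resolution modularity search
#' finds one organisational scale; sweeping the resolution reveals multiple
#' significant scales (p-value troughs) when the society is hierarchically
#' tiered. One ensemble is reused across all resolutions.
#'
#' @param A An `assoc_matrix` (simple-ratio by convention; BP null p-values
#'   are typically too extreme to vary usefully).
#' @param ensemble A `null_ensemble` of matching index type.
#' @param gammas Resolutions to scan (default 0 to 2 in steps of 0.01).
#' @param seed Optional RNG seed.
#' @param restarts Node-order restarts per optimisation (default 3; the
#'   sweep multiplies work by the resolution grid and ensemble size).
#' @param units_info Optional unit metadata.
#' @return Data frame with one row per gamma: `gamma`, `Q`, `p`,
#'   `n_modules`, `mean_units`, `mean_individuals`.
#' @export
resolution_sweep <- function(A, ensemble, gammas = seq(0, 2, by = 0.01),
                             seed = NULL, restarts = 3L, units_info = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(gammas, function(gam) {
    obs <- louvain(A, gamma = gam, restarts = restarts,
                   units_info = units_info)
    null_q <- vapply(ensemble$matrices, function(nm) {
      louvain(nm, gamma = gam, restarts = restarts)$Q
    }, numeric(1))
    data.frame(
      gamma = gam, Q = obs$Q,
      p = empirical_p(obs$Q, null_q, "ge"),
      n_modules = obs$partition$n_clusters,
      mean_units = obs$partition$mean_units,
      mean_individuals = obs$partition$mean_individuals
    )
  })
  do.call(rbind, rows)
}

#' Locate significant p-value troughs in a resolution sweep
#'
#' A trough is a maximal contiguous run of resolutions whose empirical
#' p-value falls below `alpha`; each trough is summarised by its most
#' significant resolution (smallest p, ties broken toward smaller gamma).
#' Two separated troughs indicate two distinct organisational scales.
#'
#' @param sweep Data frame from [resolution_sweep()].
#' @param alpha Significance threshold (default 0.05).
#' @return Data frame of trough summaries (possibly zero rows): the sweep
#'   row at each trough's most significant gamma, plus `gamma_lo`/`gamma_hi`
#'   bounds of the run.
#' @export
find_troughs <- function(sweep, alpha = 0.05) {
  if (nrow(sweep) < 3L) stop("sweep must cover at least 3 resolutions")
  sig <- sweep$p < alpha
  out <- list()
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    run <- sweep[starts[i]:ends[i], , drop = FALSE]
    best <- run[which.min(run$p), , drop = FALSE]
    best$gamma_lo <- run$gamma[1]
    best$gamma_hi <- run$gamma[nrow(run)]
    out[[length(out) + 1L]] <- best
  }
  if (length(out) == 0L)
    return(sweep[0, c("gamma", "Q", "p", "n_modules", "mean_units",
                      "mean_individuals")])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-method consistency of tier assignments
#'
#' Logistic regression over all unordered unit pairs of tier-2
#' co-membership (same module from modularity analysis) on tier-1
#' co-membership (same cluster from hierarchical clustering). A strongly
#' positive slope means the tiers are hierarchically inclusive: pairs
#' sharing a first-tier cluster sit inside the same second-tier module.
#' Dyadic observations are not independent; the Wald z is reported as a
#' descriptive consistency statistic, as is conventional for this check.
#'
#' @param tier1,tier2 `tier_partition` objects over the same unit set.
#' @return List with `z`, `p` (two-sided Wald), `n_pairs`, `separated`
#'   (TRUE when the 2x2 pair table has an empty cell, making the slope
#'   infinite; `z` is then NA).
#' @export
comembership_glm <- function(tier1, tier2) {
  units <- intersect(names(tier1$assignment), names(tier2$assignment))
  if (length(units) < 3L) stop("need at least 3 shared units")
  pairs <- combn(units, 2L)
  same1 <- as.integer(tier1$assignment[pairs[1, ]] ==
                        tier1$assignment[pairs[2, ]])
  same2 <- as.integer(tier2$assignment[pairs[1, ]] ==
                        tier2$assignment[pairs[2, ]])
  tab <- table(factor(same1, levels = 0:1), factor(same2, levels = 0:1))
  if (any(tab == 0L)) {
    warning("complete separation: infinite slope in co-membership regression")
    return(list(z = NA_real_, p = NA_real_, n_pairs = ncol(pairs),
                separated = TRUE, table = tab,
                z_corrected = haldane_z(tab)))
  }
  fit <- glm(same2 ~ same1, family = binomial())
  s <- summary(fit)$coefficients["same1", ]
  list(z = unname(s["z value"]), p = unname(s["Pr(>|z|)"]),
       n_pairs = ncol(pairs), separated = FALSE, table = tab,
       z_corrected = haldane_z(tab))
}

#' Haldane-Anscombe corrected Wald z of a 2x2 table (internal)
#'
#' Log odds ratio over its standard error with 0.5 added to every cell;
#' finite even under complete separation, where the plain Wald z is not.
#' @keywords internal
haldane_z <- function(tab) {
  t2 <- tab + 0.5
  lor <- log(t2["1", "1"] * t2["0", "0"] / (t2["1", "0"] * t2["0", "1"]))
  unname(lor / sqrt(sum(1 / t2)))
}
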