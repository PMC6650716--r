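# Fixture builders and independent oracles used across test files.

# Presence matrix from a named list of visit-day sets (0-based days).
presence_from_sets <- function(day_sets, T_days) {
  units <- names(day_sets)
  pm <- matrix(0L, length(units), T_days,
               dimnames = list(units, as.character(0:(T_days - 1))))
  for (u in units) pm[u, as.character(day_sets[[u]])] <- 1L
  pm
}

visits_from_sets <- function(day_sets) {
  do.call(rbind, lapply(names(day_sets), function(u) {
    data.frame(unit_id = u, day = as.integer(day_sets[[u]]),
               stringsAsFactors = FALSE)
  }))
}

# Oracle: Jaccard index of two day sets.
jaccard_sets <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) 0 else length(intersect(a, b)) / u
}

# Oracle: binomial upper tail P(X >= k) by direct pmf summation.
binom_tail_sum <- function(k, T_days, p) {
  if (k <= 0) return(1)
  if (k > T_days) return(0)
  sum(choose(T_days, k:T_days) * p^(k:T_days) * (1 - p)^(T_days - (k:T_days)))
}

# Oracle: naive average-linkage agglomeration returning the cophenetic
# distance matrix (merge pair chosen as the minimum average distance,
# lowest-index tie-break).
upgma_cophenetic_oracle <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = dimnames(D))
  avg_dist <- function(a, b) mean(D[a, b])
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1L):length(clusters)) {
        d <- avg_dist(clusters[[i]], clusters[[j]])
        if (d < best_d - 1e-12) { best_d <- d; best <- c(i, j) }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_d; coph[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Oracle: exact Poisson-binomial pmf by direct polynomial multiplication
# (no FFT, so tiny tail coefficients keep full relative precision).
poisbinom_pmf_oracle <- function(q) {
  dist <- 1
  for (qt in q) {
    dist <- c(dist * (1 - qt), 0) + c(0, dist * qt)
  }
  dist
}

# Enumerate all permutations of 1..n (recursive insertion).
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  shorter <- all_permutations(n - 1L)
  out <- list()
  for (p in shorter) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Enumerate all set partitions of n elements (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, k) {
    i <- length(labels) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- labels; return(invisible()) }
    for (lab in seq_len(k + 1L)) rec(c(labels, lab), max(k, lab))
  }
  rec(integer(0), 0L)
  out
}

# Oracle: weighted modularity of a partition at resolution gamma, from the
# definition Q = sum_c [w_c/W - gamma * (s_c / 2W)^2].
modularity_oracle <- function(m, membership, gamma = 1) {
  diag(m) <- 0
  W <- sum(m) / 2
  strength <- rowSums(m)
  q <- 0
  for (c in unique(membership)) {
    idx <- which(membership == c)
    w_c <- sum(m[idx, idx, drop = FALSE]) / 2
    s_c <- sum(strength[idx])
    q <- q + w_c / W - gamma * (s_c / (2 * W))^2
  }
  q
}

# Oracle: best modularity over every partition of <=n nodes.
best_partition_oracle <- function(m, gamma = 1) {
  parts <- all_partitions(nrow(m))
  qs <- vapply(parts, function(p) modularity_oracle(m, p, gamma), numeric(1))
  list(Q = max(qs), membership = parts[[which.max(qs)]])
}

# Small synthetic study used by several files: strong planted structure,
# modest size so tests stay fast.
small_study <- function(seed, n_units = 24, T_days = 365, ...) {
  cfg <- generator_config(n_units = n_units, T_days = T_days, ...)
  truth <- generate_population(cfg, seed = seed)
  visits <- suppressMessages(simulate_visits(truth, seed = seed + 5000))
  pm <- filter_min_visits(
    build_presence(visits, study_period("s", 0, cfg$T_days - 1)))
  list(cfg = cfg, truth = truth, visits = visits, pm = pm)
}
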