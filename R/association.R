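#' Association matrix constructor (internal)
#'
#' An association matrix couples a symmetric matrix of pairwise association
#' values in [0, 1] ("bigger = closer") with its index type. For the
#' binomial-probability index the matrix of upper-tail probabilities is kept
#' alongside, because hierarchical clustering consumes the tail as a
#' distance.
#'
#' @param values Symmetric numeric matrix, zero diagonal.
#' @param index_type `"SR"` or `"BP"`.
#' @param tail Optional matrix of tail probabilities (BP only).
#' @return Object of class `assoc_matrix`.
#' @keywords internal
assoc_matrix <- function(values, index_type, tail = NULL) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  index_type <- match.arg(index_type, c("SR", "BP"))
  structure(
    list(units = rownames(values), values = values,
         index_type = index_type, tail = tail),
    class = "assoc_matrix"
  )
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("%s association matrix: %d units, mean off-diagonal %.4f\n",
              x$index_type, nrow(x$values),
              mean(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' @export
as.matrix.assoc_matrix <- function(x, ...) x$values

#' Simple-ratio association index
#'
#' For each pair of units, the number of days both visited divided by the
#' number of days at least one visited: the day-level Jaccard coefficient of
#' their visit-day sets, the standard "gambit of the group" index at one-day
#' sampling periods. Pairs never observed at all score 0.
#'
#' @param pm Presence matrix from [build_presence()].
#' @return An `assoc_matrix` with `index_type = "SR"`.
#' @export
simple_ratio <- function(pm) {
  if (nrow(pm) < 2L) stop("need at least 2 units")
  k <- tcrossprod(pm)            # covisit counts
  v <- rowSums(pm)
  denom <- outer(v, v, "+") - k  # days at least one visited
  sr <- ifelse(denom > 0, k / denom, 0)
  diag(sr) <- 0
  assoc_matrix(sr, "SR")
}

#' Binomial-probability association index
#'
#' For each pair of units the upper-tail probability that they would covisit
#' at least the observed number of days if each visited independently at its
#' average rate: `p_ij = P(X >= k_ij)` with
#' `X ~ Binomial(T, (v_i/T)(v_j/T))`, where `T` is the number of observation
#' days, `v_i` the visit counts and `k_ij` the observed covisit count. A
#' small tail means the pair covisits far more than chance; the association
#' value is `1 - p_ij` so that larger means closer.
#'
#' With `rate_adjust = TRUE` the per-day covisit probability is modulated by
#' the squared relative daily attendance `s_t` (attendance on day t divided
#' by mean daily attendance), rescaled so its mean equals the unadjusted
#' rate, and the tail comes from the exact Poisson-binomial distribution.
#' This corrects for population-wide fluctuation in visitation (e.g.
#' seasonality), which otherwise manufactures spurious association: on busy
#' days every pair is more likely to covisit. With constant attendance the
#' adjusted index equals the plain one.
#'
#' @param pm Presence matrix; every unit must have at least one visit
#'   (apply [filter_min_visits()] first).
#' @param rate_adjust Correct for daily attendance fluctuation?
#' @return An `assoc_matrix` with `index_type = "BP"`; the tail
#'   probabilities are in `$tail`.
#' @export
binomial_probability <- function(pm, rate_adjust = FALSE) {
  if (nrow(pm) < 2L) stop("need at least 2 units")
  T_days <- ncol(pm)
  if (T_days < 1L) stop("need at least 1 observation day")
  v <- rowSums(pm)
  if (any(v == 0))
    stop("units with zero visits present; apply filter_min_visits() first")
  k <- tcrossprod(pm)
  n <- nrow(pm)
  tail <- matrix(1, n, n, dimnames = dimnames(k))
  if (rate_adjust) {
    att <- colSums(pm)
    s2 <- (att / mean(att))^2
    s2 <- s2 / mean(s2) # unit mean: adjustment redistributes, not inflates
  }
  n_clamped <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p_base <- (v[i] / T_days) * (v[j] / T_days)
      if (rate_adjust) {
        q <- p_base * s2
        over <- q > 1
        if (any(over)) {
          n_clamped <- n_clamped + sum(over)
          q[over] <- 1
        }
        p_ij <- poisbinom_tail(q, k[i, j])
      } else {
        p_ij <- pbinom(k[i, j] - 1L, T_days, p_base, lower.tail = FALSE)
      }
      tail[i, j] <- tail[j, i] <- p_ij
    }
  }
  if (n_clamped > 0L)
    warning(sprintf("%d per-day covisit probabilities exceeded 1 and were clamped",
                    n_clamped))
  values <- 1 - tail
  diag(values) <- 0
  assoc_matrix(values, "BP", tail = tail)
}

#' Mantel matrix-correlation test
#'
#' Measures agreement between two association matrices over their shared
#' units: the statistic Z is the Pearson correlation of the off-diagonal
#' upper triangles, and its p-value comes from simultaneous row/column
#' relabelings of the second matrix (add-one permutation convention, upper
#' tail). Used to test the stability of pairwise associations across
#' consecutive study periods.
#'
#' @param A,B `assoc_matrix` objects (or plain labeled matrices).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional RNG seed.
#' @return Object of class `mantel_result` with fields `Z`, `p`, `n_perm`,
#'   `n_units`.
#' @export
mantel_association <- function(A, B, n_perm = 1000L, seed = NULL) {
  ma <- if (inherits(A, "assoc_matrix")) A$values else A
  mb <- if (inherits(B, "assoc_matrix")) B$values else B
  shared <- intersect(rownames(ma), rownames(mb))
  if (length(shared) < 3L)
    stop("need at least 3 shared units for a Mantel test")
  ma <- ma[shared, shared]
  mb <- mb[shared, shared]
  ut <- upper.tri(ma)
  if (sd(ma[ut]) == 0 || sd(mb[ut]) == 0)
    stop("constant association matrix: Mantel Z undefined")
  z_obs <- cor(ma[ut], mb[ut])
  if (!is.null(seed)) set.seed(seed)
  n <- length(shared)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    zb <- cor(ma[ut], mb[perm, perm][ut])
    if (zb >= z_obs) hits <- hits + 1L
  }
  structure(
    list(Z = z_obs, p = (1 + hits) / (1 + n_perm),
         n_perm = as.integer(n_perm), n_units = n),
    class = "mantel_result"
  )
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test on %d shared units: Z = %.3f, p = %.4g (%d permutations)\n",
              x$n_units, x$Z, x$p, x$n_perm))
  invisible(x)
}

#' Write an association matrix to CSV
#'
#' @param A An `assoc_matrix`.
#' @param path Output path.
#' @export
write_association <- function(A, path) {
  write.csv(as.data.frame(A$values), path, row.names = TRUE)
  invisible(path)
}

#' Read an association matrix from CSV
#'
#' Accepts either a square labeled matrix (as written by
#' [write_association()]) or a long-format edge list with columns
#' `unit_a,unit_b,value`.
#'
#' @param path Input path.
#' @param index_type `"SR"` or `"BP"`. For BP input the values are taken to
#'   be association values `1 - tail` and the tail is reconstructed.
#' @return An `assoc_matrix`.
#' @export
read_association <- function(path, index_type = c("SR", "BP")) {
  index_type <- match.arg(index_type)
  header <- names(read.csv(path, nrows = 1, check.names = FALSE))
  if (identical(sort(header), sort(c("unit_a", "unit_b", "value")))) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    units <- sort(unique(c(df$unit_a, df$unit_b)))
    m <- matrix(0, length(units), length(units),
                dimnames = list(units, units))
    m[cbind(match(df$unit_a, units), match(df$unit_b, units))] <- df$value
    m[cbind(match(df$unit_b, units), match(df$unit_a, units))] <- df$value
  } else {
    m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
    colnames(m) <- rownames(m)
  }
  diag(m) <- 0
  tail <- if (index_type == "BP") {
    tl <- 1 - m; diag(tl) <- 1; tl
  } else NULL
  assoc_matrix(m, index_type, tail = tail)
}
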