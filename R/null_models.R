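#' Data-stream permutation of a presence matrix
#'
#' Randomizes which days units visited while preserving every unit's visit
#' count and every day's attendance, by checkerboard swaps: repeatedly pick
#' two units and two days whose 2x2 submatrix is `[[1,0],[0,1]]` or
#' `[[0,1],[1,0]]` and flip it. This is the permutation null for the
#' simple-ratio index: it destroys pairwise covisit structure but keeps the
#' gregariousness of units and the busyness of days.
#'
#' @param pm Presence matrix.
#' @param n_swaps Number of successful swaps to perform.
#' @param seed Optional RNG seed.
#' @param max_attempts Proposal cap before giving up (default `100 *
#'   n_swaps + 1000`); degenerate margins with no swappable submatrix
#'   return early with a warning.
#' @return Permuted presence matrix with attribute `"swaps_done"`.
#' @export
datastream_permute <- function(pm, n_swaps, seed = NULL,
                               max_attempts = 100 * n_swaps + 1000) {
  if (!is.null(seed)) set.seed(seed)
  out <- cb_swap_chain(pm, as.integer(n_swaps), max_attempts)
  dimnames(out) <- dimnames(pm)
  if (attr(out, "swaps_done") < n_swaps)
    warning(sprintf("only %d of %d swaps achieved within the attempt cap",
                    as.integer(attr(out, "swaps_done")), as.integer(n_swaps)))
  attr(out, "period") <- attr(pm, "period")
  out
}

#' Null ensemble of association matrices
#'
#' Generates `n` association matrices under the no-preference null. For the
#' simple-ratio index this is a sequential data-stream permutation chain
#' (checkerboard swaps with thinning: one matrix retained every
#' `swaps_per_sample` successful swaps). For the binomial-probability index,
#' whose null conditions only on each unit's total visit count, every sample
#' redraws each unit's visit days as a uniform random subset of the
#' observation days of the same size, then recomputes the index.
#'
#' @param pm Presence matrix (already filtered).
#' @param index_type `"SR"` or `"BP"`.
#' @param n Ensemble size (default 1000).
#' @param swaps_per_sample Successful swaps between retained SR samples
#'   (default 500).
#' @param seed Optional RNG seed.
#' @param rate_adjust Passed to [binomial_probability()] for BP ensembles.
#' @return Object of class `null_ensemble`: list with `index_type`,
#'   `matrices` (list of `assoc_matrix`), `n`, `seed`, `method`.
#' @export
null_ensemble <- function(pm, index_type = c("SR", "BP"), n = 1000L,
                          swaps_per_sample = 500L, seed = NULL,
                          rate_adjust = FALSE) {
  index_type <- match.arg(index_type)
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  mats <- vector("list", n)
  if (index_type == "SR") {
    cur <- pm
    for (b in seq_len(n)) {
      cur <- datastream_permute(cur, swaps_per_sample)
      mats[[b]] <- simple_ratio(cur)
    }
    method <- "datastream"
  } else {
    T_days <- ncol(pm)
    v <- rowSums(pm)
    for (b in seq_len(n)) {
      null_pm <- pm
      null_pm[] <- 0L
      for (i in seq_len(nrow(pm)))
        null_pm[i, sample.int(T_days, v[i])] <- 1L
      mats[[b]] <- binomial_probability(null_pm, rate_adjust = rate_adjust)
    }
    method <- "parametric"
  }
  structure(
    list(index_type = index_type, matrices = mats, n = as.integer(n),
         seed = seed, method = method,
         swaps_per_sample = as.integer(swaps_per_sample)),
    class = "null_ensemble"
  )
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null ensemble: %d %s matrices (%s method)\n",
              x$n, x$index_type, x$method))
  invisible(x)
}

#' Empirical permutation p-value
#'
#' Add-one convention: `(1 + #nulls at least as extreme) / (1 + n)`, so the
#' p-value is never exactly zero and ties with the observed value count as
#' extreme.
#'
#' @param observed Observed scalar statistic.
#' @param null_values Numeric vector of null statistics.
#' @param direction `"ge"` if large values are extreme, `"le"` otherwise.
#' @return Empirical p-value in (0, 1].
#' @export
empirical_p <- function(observed, null_values, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  if (length(null_values) < 1L) stop("need at least one null value")
  hits <- if (direction == "ge") sum(null_values >= observed)
          else sum(null_values <= observed)
  (1 + hits) / (1 + length(null_values))
}

#' Persist a null ensemble to a directory
#'
#' Writes each null association matrix as a CSV plus a JSON manifest
#' recording the method, size, seed and thinning interval.
#'
#' @param ens A `null_ensemble`.
#' @param dir Output directory (created if needed).
#' @export
write_ensemble <- function(ens, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in seq_len(ens$n))
    write_association(ens$matrices[[b]],
                      file.path(dir, sprintf("null_%04d.csv", b)))
  manifest <- list(index_type = ens$index_type, n = ens$n,
                   method = ens$method, seed = ens$seed,
                   swaps_per_sample = ens$swaps_per_sample)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}
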