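test_that("simple ratio matches hand-enumerated day sets", {
  pm <- presence_from_sets(list(i = 1:3, j = 2:4, k = 6:8), 10)
  sr <- simple_ratio(pm)$values
  expect_equal(sr["i", "j"], 0.5)    # x=2, y_i=1, y_j=1
  expect_equal(sr["i", "k"], 0)      # disjoint
  same <- presence_from_sets(list(a = 1:4, b = 1:4), 10)
  expect_equal(simple_ratio(same)$values["a", "b"], 1)
  expect_equal(unname(diag(sr)), c(0, 0, 0))
})

test_that("simple ratio equals the set-based Jaccard oracle on random fixtures", {
  set.seed(7)
  for (rep in 1:10) {
    sets <- lapply(setNames(1:6, paste0("u", 1:6)),
                   function(i) sample(0:19, sample(1:15, 1)))
    sr <- simple_ratio(presence_from_sets(sets, 20))$values
    for (i in 1:5) for (j in (i + 1):6) {
      expect_equal(sr[i, j], jaccard_sets(sets[[i]], sets[[j]]))
    }
  }
})

test_that("plain BP tail equals direct binomial pmf summation", {
  # spec'd case: T=10, v_i=5, v_j=4, k=4
  pm <- presence_from_sets(list(i = 0:4, j = c(0:3)), 10)
  bp <- binomial_probability(pm)
  expect_equal(bp$tail["i", "j"], binom_tail_sum(4, 10, 0.2),
               tolerance = 1e-12)
  expect_equal(bp$values["i", "j"], 1 - bp$tail["i", "j"])

  # never covisit -> tail 1, association 0
  pm0 <- presence_from_sets(list(i = 0:2, j = 3:5), 10)
  bp0 <- binomial_probability(pm0)
  expect_equal(unname(bp0$tail["i", "j"]), 1)
  expect_equal(unname(bp0$values["i", "j"]), 0)

  # both visit every day: k = T is certain under the null, tail = 1
  pmF <- presence_from_sets(list(i = 0:9, j = 0:9), 10)
  expect_equal(unname(binomial_probability(pmF)$tail["i", "j"]), 1)
})

test_that("BP tail matches enumeration over a (T, v_i, v_j, k) grid", {
  for (T_days in c(5, 12, 30)) {
    for (vi in c(1, 3, T_days %/% 2)) {
      for (vj in c(2, T_days %/% 3 + 1)) {
        overlaps <- unique(c(0, 1, min(vi, vj) %/% 2, min(vi, vj)))
        for (k in overlaps) {
          di <- 0:(vi - 1)
          dj <- c(if (k > 0) 0:(k - 1),
                  if (vj > k) vi + 0:(vj - k - 1))
          pm <- presence_from_sets(list(i = di, j = dj), T_days)
          got <- binomial_probability(pm)$tail["i", "j"]
          want <- binom_tail_sum(k, T_days, (vi / T_days) * (vj / T_days))
          expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
        }
      }
    }
  }
})

test_that("association value is monotone in the covisit count", {
  T_days <- 20; vi <- 8; vj <- 6
  vals <- vapply(0:6, function(k) {
    di <- 0:(vi - 1)
    dj <- c(if (k > 0) 0:(k - 1), if (vj > k) vi + 0:(vj - k - 1))
    binomial_probability(
      presence_from_sets(list(i = di, j = dj), T_days))$values["i", "j"]
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("rate-adjusted BP reproduces plain mode under constant attendance", {
  # equal per-day attendance: units visit disjoint blocks of equal width
  pm <- rbind(a = rep(c(1L, 0L), each = 10),
              b = rep(c(0L, 1L), each = 10),
              c = rep(c(1L, 0L), 10),
              d = rep(c(0L, 1L), 10))
  colnames(pm) <- as.character(0:19)
  stopifnot(sd(colSums(pm)) == 0)
  plain <- binomial_probability(pm)
  adj <- binomial_probability(pm, rate_adjust = TRUE)
  expect_equal(adj$tail, plain$tail, tolerance = 1e-12)
})

test_that("Poisson-binomial tail is exact against convolution on small cases", {
  set.seed(11)
  for (rep in 1:20) {
    q <- runif(sample(3:9, 1))
    dist <- poisbinom_pmf_oracle(q)
    for (k in 0:length(q)) {
      expect_equal(hsmnet:::poisbinom_tail(q, k),
                   sum(dist[(k + 1):length(dist)]), tolerance = 1e-12)
    }
  }
})

test_that("Mantel Z and p behave per the permutation definition", {
  set.seed(3)
  m <- matrix(runif(16), 4, 4); m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(letters[1:4], letters[1:4])
  A <- hsmnet:::assoc_matrix(m, "SR")
  self <- mantel_association(A, A, n_perm = 99, seed = 1)
  expect_equal(self$Z, 1)

  const <- hsmnet:::assoc_matrix(matrix(0.5, 4, 4,
                                        dimnames = dimnames(m)), "SR")
  expect_error(mantel_association(A, const), "constant")

  expect_error(mantel_association(A, hsmnet:::assoc_matrix(
    m[1:2, 1:2], "SR")), "3 shared units")
})

test_that("Mantel p matches exhaustive enumeration of all 24 relabelings", {
  set.seed(9)
  mk <- function() {
    m <- matrix(runif(16), 4, 4); m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(letters[1:4], letters[1:4])
    m
  }
  ma <- mk(); mb <- mk()
  ut <- upper.tri(ma)
  z_obs <- cor(ma[ut], mb[ut])
  z_all <- vapply(all_permutations(4),
                  function(p) cor(ma[ut], mb[p, p][ut]), numeric(1))
  p_exact <- mean(z_all >= z_obs)  # exhaustive null, uniform over relabelings

  res <- mantel_association(hsmnet:::assoc_matrix(ma, "SR"),
                            hsmnet:::assoc_matrix(mb, "SR"),
                            n_perm = 4000, seed = 2)
  expect_equal(res$Z, z_obs)
  expect_lt(abs(res$p - p_exact), 0.03)
})

test_that("Mantel statistic agrees with vegan's Pearson Mantel r", {
  skip_if_not_installed("vegan")
  set.seed(21)
  m1 <- matrix(runif(64), 8, 8); m1 <- (m1 + t(m1)) / 2; diag(m1) <- 0
  m2 <- matrix(runif(64), 8, 8); m2 <- (m2 + t(m2)) / 2; diag(m2) <- 0
  dimnames(m1) <- dimnames(m2) <- list(letters[1:8], letters[1:8])
  ours <- mantel_association(hsmnet:::assoc_matrix(m1, "SR"),
                             hsmnet:::assoc_matrix(m2, "SR"),
                             n_perm = 99, seed = 1)
  ref <- vegan::mantel(as.dist(m1), as.dist(m2), permutations = 99)
  expect_equal(ours$Z, unname(ref$statistic), tolerance = 1e-12)
})

test_that("association CSV export/import round-trips both layouts", {
  pm <- presence_from_sets(list(a = 0:4, b = 3:7, c = c(0, 9)), 10)
  sr <- simple_ratio(pm)
  f <- withr::local_tempfile(fileext = ".csv")
  write_association(sr, f)
  back <- read_association(f, "SR")
  expect_equal(back$values, sr$values, tolerance = 1e-12)

  # long-format edge list
  el <- data.frame(unit_a = c("a", "a", "b"), unit_b = c("b", "c", "c"),
                   value = c(0.25, 0.5, 0))
  write.csv(el, f, row.names = FALSE)
  long <- read_association(f, "SR")
  expect_equal(long$values["a", "b"], 0.25)
  expect_equal(long$values["c", "a"], 0.5)
})
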