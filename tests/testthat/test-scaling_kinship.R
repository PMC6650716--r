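units_fixture <- function(sizes) {
  data.frame(unit_id = names(sizes),
             kind = ifelse(sizes == 1, "solitary", "group"),
             n_individuals = as.integer(sizes),
             silverback_id = paste0("sb_", names(sizes)),
             stringsAsFactors = FALSE)
}

test_that("tier_sizes assembles levels from partitions and config", {
  sizes <- setNames(c(4, 6, 1, 1, 8, 4), letters[1:6])
  ui <- units_fixture(sizes)
  t1 <- hsmnet:::tier_partition(1L, setNames(c(1, 1, 2, 3, 4, 4),
                                             letters[1:6]), ui)
  t2 <- hsmnet:::tier_partition(2L, setNames(c(1, 1, 1, 2, 2, 2),
                                             letters[1:6]), ui)
  tab <- suppressWarnings(tier_sizes(t1, t2, ui))
  expect_equal(tab$level, c(1L, 3L, 4L, 5L))
  expect_equal(tab$size[tab$level == 1], 1)
  expect_equal(tab$size[tab$level == 3], mean(sizes))
  expect_equal(tab$size[tab$level == 4], mean(c(10, 1, 1, 12)))
  expect_equal(tab$size[tab$level == 5], mean(c(11, 13)))

  full <- tier_sizes(t1, t2, ui, extra_levels = c("2" = 2.5, "6" = 60,
                                                  "7" = 120))
  expect_equal(full$level, 1:7)
  ws <- testthat::capture_warnings(
    tier_sizes(t1, t2, ui, extra_levels = c("2" = 2.5)))
  expect_true(any(grepl("level 6", ws)))
  expect_true(any(grepl("level 7", ws)))
})

test_that("all-solitary populations have mean unit size 1 at level 3", {
  sizes <- setNames(rep(1, 4), letters[1:4])
  ui <- units_fixture(sizes)
  t1 <- hsmnet:::tier_partition(1L, setNames(c(1, 1, 2, 2), letters[1:4]), ui)
  t2 <- hsmnet:::tier_partition(2L, setNames(rep(1, 4), letters[1:4]), ui)
  tab <- suppressWarnings(tier_sizes(t1, t2, ui))
  expect_equal(tab$size[tab$level == 3], 1)
})

test_that("scaling_fit recovers an exact geometric series to machine precision", {
  tab <- data.frame(population = "x", level = 1:4, size = c(1, 3, 9, 27))
  fit <- scaling_fit(tab)
  expect_equal(fit$ratio, 3, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n_points, 4L)
  expect_error(scaling_fit(data.frame(population = "x", level = 1:3,
                                      size = c(1, 0, 4))), "positive")
  expect_error(scaling_fit(data.frame(population = "x", level = 1:2,
                                      size = c(1, 2))), "3 levels")
})

test_that("multi-population fits support mean-then-fit and pooled modes", {
  tab <- rbind(
    data.frame(population = "P", level = 1:4, size = c(1, 2, 4, 8)),
    data.frame(population = "Q", level = 1:4, size = 2 * c(1, 2, 4, 8))
  )
  fit_mean <- scaling_fit(tab, combine = "mean")
  expect_equal(fit_mean$ratio, 2, tolerance = 1e-12)
  expect_equal(fit_mean$r_squared, 1, tolerance = 1e-12)
  fit_pool <- scaling_fit(tab, combine = "pool")
  # population intercepts absorb the 2x offset, leaving the common slope
  expect_equal(fit_pool$ratio, 2, tolerance = 1e-12)
})

test_that("scaling ratio recovers the planted multiplier on synthetic truth", {
  set.seed(53)
  ratios <- replicate(10, {
    truth <- generate_population(generator_config())
    scaling_fit(true_tier_sizes(truth))$ratio
  })
  # four levels spanning 1 .. ~40 individuals: ratio should sit in the
  # characteristic 2.5-4 band of multi-level societies
  expect_true(all(ratios > 2 & ratios < 5))
  tab1 <- true_tier_sizes(generate_population(generator_config(), seed = 3))
  fit <- scaling_fit(tab1)
  expect_gt(fit$r_squared, 0.9)
})

test_that("kinship regression matches the 2x2 Wald oracle and flags separation", {
  sizes <- setNames(c(4, 6, 1, 1, 8, 4, 2, 3), letters[1:8])
  ui <- units_fixture(sizes)
  part <- hsmnet:::tier_partition(2L, setNames(c(1, 1, 1, 1, 2, 2, 2, 2),
                                               letters[1:8]), ui)
  pairs <- t(combn(letters[1:8], 2))
  set.seed(59)
  same <- part$assignment[pairs[, 1]] == part$assignment[pairs[, 2]]
  related <- ifelse(same, rbinom(nrow(pairs), 1, 0.6),
                    rbinom(nrow(pairs), 1, 0.2))
  kin <- data.frame(silverback_a = paste0("sb_", pairs[, 1]),
                    silverback_b = paste0("sb_", pairs[, 2]),
                    related = related)
  res <- kinship_glm(kin, part, ui)
  tab <- res$table
  log_or <- log(tab["1", "1"] * tab["0", "0"] / (tab["1", "0"] * tab["0", "1"]))
  expect_equal(res$z, log_or / sqrt(sum(1 / tab)), tolerance = 1e-6)
  expect_equal(res$related_fraction,
               mean(related[same]), tolerance = 1e-12)
  expect_equal(res$n_pairs, 28L)

  # all related pairs co-resident, all unrelated pairs split -> separation
  kin2 <- data.frame(silverback_a = paste0("sb_", pairs[, 1]),
                     silverback_b = paste0("sb_", pairs[, 2]),
                     related = as.integer(same))
  expect_warning(sep <- kinship_glm(kin2, part, ui), "separation")
  expect_true(sep$separated)
  expect_equal(sep$related_fraction, 1)
})

test_that("kinship unrelated to modules gives uniform-ish p over replicates", {
  sizes <- setNames(rep(c(1, 5), 6), letters[1:12])
  ui <- units_fixture(sizes)
  part <- hsmnet:::tier_partition(2L, setNames(rep(1:3, each = 4),
                                               letters[1:12]), ui)
  pairs <- t(combn(letters[1:12], 2))
  set.seed(61)
  ps <- replicate(40, {
    kin <- data.frame(silverback_a = paste0("sb_", pairs[, 1]),
                      silverback_b = paste0("sb_", pairs[, 2]),
                      related = rbinom(nrow(pairs), 1, 0.4))
    r <- suppressWarnings(kinship_glm(kin, part, ui))
    if (r$separated) NA else r$p
  })
  ps <- ps[!is.na(ps)]
  expect_gt(length(ps), 30)
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.3)
})

test_that("kinship input validation catches unusable data", {
  sizes <- setNames(c(2, 3, 4), c("a", "b", "c"))
  ui <- units_fixture(sizes)
  part <- hsmnet:::tier_partition(2L, setNames(c(1, 2, 3), c("a", "b", "c")),
                                  ui)
  kin <- data.frame(silverback_a = c("sb_a", "sb_a", "sb_b"),
                    silverback_b = c("sb_b", "sb_c", "sb_c"),
                    related = c(1L, 0L, 0L))
  expect_error(kinship_glm(kin, part, ui), "same-module")
  expect_error(kinship_glm(kin[1:2, ], part, ui), "3 kinship pairs")
})
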