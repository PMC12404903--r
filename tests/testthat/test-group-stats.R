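test_that("per-animal aggregation averages sections", {
  d <- data.frame(animal_id = c("a", "a", "a", "b"), stage = "diestrus",
                  region = "ARN", section_id = c(1:3, 1),
                  cells_positive = c(10L, 12L, 14L, 7L))
  am <- aggregate_per_animal(d)
  expect_identical(am$mean_cells_per_section, c(12, 7))

  cfg <- group_sim_config(deterministic = TRUE, animal_effect_sd_log = 0,
                          regions = "ARN")
  am2 <- aggregate_per_animal(simulate_group_counts(cfg))
  expect_true(all(am2$mean_cells_per_section[am2$stage == "diestrus"] == 12))
})

test_that("Kruskal-Wallis reproduces hand-computed statistics", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_identical(kw$df, 2L)
  expect_equal(kw$p, pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(kw$group_summary$mean_rank, c(2, 5, 8))

  kw2 <- kruskal_wallis(list(c(1, 3, 5), c(2, 4, 6)))
  expect_equal(kw2$H, 3 / 7, tolerance = 1e-12)   # 0.4286

  kw3 <- kruskal_wallis(list(c(4, 4), c(4, 4, 4)))
  expect_identical(kw3$H, 0)
  expect_identical(kw3$p, 1)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("tie-corrected H agrees with stats::kruskal.test on random data", {
  set.seed(61)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(g)
      sample(0:8, sample(3:8, 1), replace = TRUE))  # heavy ties
    if (length(unique(unlist(groups))) < 2) next
    kw <- kruskal_wallis(groups)
    ref <- stats::kruskal.test(unlist(groups),
                               factor(rep(seq_len(k), lengths(groups))))
    expect_equal(kw$H, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(kw$p, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(62)
  groups <- lapply(1:3, function(g) rgamma(5, 2) + g)
  h0 <- kruskal_wallis(groups)$H
  for (f in list(function(x) 3 * x + 2, exp, function(x) x^3))
    expect_equal(kruskal_wallis(lapply(groups, f))$H, h0, tolerance = 1e-12)
})

test_that("Dunn's z and Bonferroni p reproduce the hand computation", {
  dn <- dunn_posthoc(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  ext <- dn[dn$group_i == "group1" & dn$group_j == "group3", ]
  expect_equal(abs(ext$z), 6 / sqrt(5), tolerance = 1e-4)       # 2.6833
  expect_equal(ext$p_adjusted, 3 * 2 * pnorm(-6 / sqrt(5)), tolerance = 1e-10)
  expect_equal(round(ext$p_adjusted, 5), 0.02187)
  expect_true(all(dn$p_adjusted >= dn$p_raw))
  expect_true(all(dn$p_adjusted == pmin(1, dn$p_raw * dn$n_comparisons)))
})

test_that("degenerate and clamped Dunn cases follow the conventions", {
  same <- dunn_posthoc(list(c(2, 2, 2), c(2, 2, 2)))
  expect_identical(same$z, 0)
  expect_identical(same$p_adjusted, 1)

  set.seed(63)
  noisy <- dunn_posthoc(lapply(1:4, function(i) rnorm(4)))
  expect_true(all(noisy$p_adjusted <= 1))
  expect_true(any(noisy$p_raw * noisy$n_comparisons > 1))  # clamping exercised
})

test_that("restricted comparison sets adjust by their own count", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  dn <- dunn_posthoc(g, comparisons = list(c("a", "c")))
  expect_identical(nrow(dn), 1L)
  expect_identical(dn$n_comparisons, 1L)
  expect_equal(dn$p_adjusted, dn$p_raw, tolerance = 1e-15)
})

test_that("chi-square p stays within 0.05 of the exact permutation p", {
  # designs with at least 3 observations per group; the chi-square
  # approximation is not expected to hold for k = 3 with pairs-only groups
  cases <- list(
    list(c(1, 2, 3), c(4, 5, 6)),
    list(c(1, 3, 5, 7), c(2, 4, 6, 8)),
    list(c(10, 20, 30), c(15, 25, 35, 45)),
    list(c(1, 4, 6), c(2, 5, 8), c(3, 7)))
  for (groups in cases) {
    p_exact <- oracle_perm_p(groups)
    p_chi <- kruskal_wallis(groups)$p
    expect_lt(abs(p_chi - p_exact), 0.05)
  }
})
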