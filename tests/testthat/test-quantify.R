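toy_rois <- function() {
  a <- array(0L, c(2, 10, 10))
  a[1, 2:4, 2:4] <- 1L
  a[2, 6:8, 6:8] <- 2L
  label_volume(a)
}

spot_row <- function(channel, z, y, x) {
  data.frame(channel = channel, z = z, y = y, x = x,
             peak_detail_adu = 12, area_px = 3L, n_planes = 1L,
             roi_label = 0L)
}

test_that("spots take the label under their rounded voxel, background gives 0", {
  rois <- toy_rois()
  sp <- rbind(spot_row(1, 1.2, 3.4, 2.6),   # rounds to (1,3,3) -> label 1
              spot_row(1, 2.0, 7.0, 7.0),   # label 2
              spot_row(2, 1.0, 9.0, 9.0))   # background
  out <- assign_spots(sp, rois)
  expect_identical(out$roi_label, c(1L, 2L, 0L))
  expect_error(assign_spots(spot_row(1, 5, 3, 3), rois), "outside")
})

test_that("tabulation enumerates every ROI and conserves assigned spots", {
  rois <- toy_rois()
  empty <- tabulate_counts(spot_row(1, 1, 1, 1)[0, ], rois)
  expect_identical(nrow(empty), 2L)
  expect_true(all(empty$count_probe1 == 0L) && all(empty$count_probe2 == 0L))

  sp <- assign_spots(rbind(spot_row(1, 1, 3, 3), spot_row(1, 1, 2, 2),
                           spot_row(1, 1, 3, 2), spot_row(2, 2, 7, 7),
                           spot_row(2, 2, 6, 6), spot_row(1, 1, 9, 9)), rois)
  tab <- tabulate_counts(sp, rois)
  expect_identical(tab$count_probe1, c(3L, 0L))
  expect_identical(tab$count_probe2, c(0L, 2L))
  # conservation: per-channel column sums equal spots assigned to cells
  expect_identical(sum(tab$count_probe1),
                   sum(sp$channel == 1 & sp$roi_label > 0L))
  expect_identical(sum(tab$count_probe2),
                   sum(sp$channel == 2 & sp$roi_label > 0L))
})

test_that("positivity threshold follows mean minus k SD with the stated conventions", {
  expect_identical(positivity_threshold(rep(7L, 6)), 7)          # zero variance
  expect_identical(positivity_threshold(c(4, 6, 8, 10, 12)), 2)  # 8 - 2*sqrt(10) -> 2
  expect_identical(positivity_threshold(c(0, 0, 12, 12)), 12)    # zeros excluded
  expect_identical(suppressWarnings(positivity_threshold(
    c(0, 0, 12, 12), positivity_rule(include_zero_cells = TRUE))), 1)
  expect_warning(positivity_threshold(c(1, 20), positivity_rule(k_sd = 2)),
                 "floored")
  expect_error(positivity_threshold(c(0, 0, 5)), "at least 2")
})

test_that("adding zero-count cells leaves the default threshold unchanged", {
  set.seed(51)
  counts <- rnbinom(200, size = 8, mu = 15) + 1L
  t1 <- positivity_threshold(counts)
  t2 <- positivity_threshold(c(counts, rep(0L, 500)))
  expect_identical(t1, t2)
  expect_gte(t1, 1)
})

test_that("classification respects the comparator and is monotone in threshold", {
  tab <- tabulate_counts(spot_row(1, 1, 1, 1)[0, ], toy_rois())
  tab$count_probe1 <- c(3L, 12L); tab$count_probe2 <- c(7L, 7L)
  ge <- classify_positive(tab, c(probe1 = 7, probe2 = 7))
  expect_identical(ge$positive_probe2, c(TRUE, TRUE))
  expect_identical(ge$positive_probe1, c(FALSE, TRUE))
  gt <- classify_positive(tab, c(probe1 = 7, probe2 = 7),
                          positivity_rule(comparator = "gt"))
  expect_identical(gt$positive_probe2, c(FALSE, FALSE))
  one <- classify_positive(tab, c(probe1 = 1, probe2 = 1))
  expect_identical(one$positive_probe1, tab$count_probe1 >= 1)
  expect_error(classify_positive(tab, c(probe1 = 0, probe2 = 7)), ">= 1")

  set.seed(52)
  tab2 <- tab[rep(1, 50), ]
  tab2$count_probe1 <- rnbinom(50, size = 2, mu = 10)
  tab2$count_probe2 <- 0L
  n_pos <- vapply(1:20, function(thr)
    sum(classify_positive(tab2, c(probe1 = thr, probe2 = 1))$positive_probe1), 0L)
  expect_true(all(diff(n_pos) <= 0L))
})

test_that("co-expression counts duals and leaves empty denominators missing", {
  tab <- data.frame(cell_id = 1:10, section_id = 1L,
                    positive_probe1 = 1:10 %in% 1:6,
                    positive_probe2 = 1:10 %in% 4:9)
  s <- coexpression_summary(tab)
  expect_identical(s$n_dual, 3L)
  expect_identical(s$pct_A_that_are_B, 50)
  expect_identical(s$pct_B_that_are_A, 50)
  expect_lte(s$n_dual, min(s$n_pos_A, s$n_pos_B))

  none <- tab; none$positive_probe1 <- FALSE
  s0 <- coexpression_summary(none)
  expect_true(is.na(s0$pct_A_that_are_B))
  expect_identical(s0$pct_B_that_are_A, 0)
})

test_that("a planted dual-positive fraction is recovered within 0.05", {
  set.seed(53)
  n <- 200
  pos_a <- runif(n) < 0.6
  dual <- pos_a & runif(n) < 0.8     # 80% of A-positives also B-positive
  tab <- data.frame(cell_id = seq_len(n), section_id = rep(1:4, each = 50),
                    positive_probe1 = pos_a, positive_probe2 = dual)
  s <- coexpression_summary(tab)
  expect_lt(abs(s$pct_A_that_are_B / 100 - 0.8), 0.05)
})

test_that("noise-free well-separated scenes recover true counts exactly", {
  for (s in 1:5) {
    sim <- simulate_stack(exact_regime_config(s + 40))
    tab <- quantify_stack(sim)
    tw <- truth_counts_wide(sim$truth)
    expect_identical(tab$count_probe1, as.integer(tw$count_p1))
    expect_identical(tab$count_probe2, as.integer(tw$count_p2))
  }
})
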