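test_that("an empty scene is a constant background volume", {
  cfg <- sim_image_config(shape_zyx = c(3L, 32L, 32L), n_nuclei = 0L,
                          poisson_noise = FALSE, read_noise_sd_adu = 0,
                          background_adu = 100)
  sim <- simulate_stack(cfg)
  expect_true(all(sim$stack$voxels == 100))
  expect_identical(nrow(sim$truth$dots), 0L)
  expect_identical(nrow(sim$truth$nuclei), 0L)
})

test_that("dot bookkeeping: dots tally to true_counts plus extracellular", {
  sim <- simulate_stack(exact_regime_config(8))
  td <- sim$truth$dots
  expect_identical(nrow(td),
                   sum(sim$truth$true_counts$count) + sum(td$cell_id == 0L))
  # per-cell tallies agree with true_counts
  for (r in seq_len(nrow(sim$truth$true_counts))) {
    tc <- sim$truth$true_counts[r, ]
    expect_identical(sum(td$cell_id == tc$cell_id & td$channel == tc$channel),
                     tc$count)
  }
})

test_that("identical seeds reproduce voxels and truth bit-for-bit", {
  cfg <- sim_image_config(shape_zyx = c(4L, 80L, 80L), n_nuclei = 10L,
                          nucleus_radius_um_range = c(2.4, 3.0), seed = 1L)
  a <- simulate_stack(cfg); b <- simulate_stack(cfg)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$dots, b$truth$dots)
  expect_identical(a$truth$true_counts, b$truth$true_counts)
  cfg2 <- cfg; cfg2$seed <- 2L
  expect_false(identical(simulate_stack(cfg2)$stack$voxels, a$stack$voxels))
})

test_that("doubling dot amplitude doubles noise-free peak height above background", {
  cfg <- exact_regime_config(9); cfg$quantize_adu <- FALSE
  cfg2 <- cfg; cfg2$dot_amplitude_adu <- 2 * cfg$dot_amplitude_adu
  v1 <- simulate_stack(cfg)$stack$voxels - cfg$background_adu
  v2 <- simulate_stack(cfg2)$stack$voxels - cfg$background_adu
  expect_lt(max(abs(v2[1:2, , , ] - 2 * v1[1:2, , , ])), 1e-9)
})

test_that("every intracellular dot sits inside its cell's dilated footprint", {
  sim <- simulate_stack(exact_regime_config(10))
  dl <- sim$truth$dilated$labels
  td <- sim$truth$dots[sim$truth$dots$cell_id > 0L, ]
  at <- dl[cbind(floor(td$z + 0.5), floor(td$y + 0.5), floor(td$x + 0.5))]
  expect_identical(at, td$cell_id)
})

test_that("impossible nucleus packing fails with the achievable count", {
  cfg <- sim_image_config(shape_zyx = c(2L, 48L, 48L), n_nuclei = 60L,
                          nucleus_radius_um_range = c(3, 3.5))
  expect_error(simulate_stack(cfg), "could only place")
})

test_that("config invariants are enforced", {
  expect_error(sim_image_config(shape_zyx = c(0, 10, 10)), "dimensions")
  expect_error(sim_image_config(nucleus_radius_um_range = c(5, 3)), "min <= max")
  expect_error(sim_image_config(dots_per_cell_dist = list(
    probe1 = list(pi0 = 1.4, mean = 5, dispersion = 1),
    probe2 = list(pi0 = 0, mean = 5, dispersion = 1))), "pi0")
})

test_that("fixtures round-trip: files, voxels, truth rows, checksums", {
  cfg <- sim_image_config(shape_zyx = c(3L, 32L, 32L), n_nuclei = 0L,
                          poisson_noise = FALSE, read_noise_sd_adu = 0)
  sim <- simulate_stack(cfg)
  d1 <- withr::local_tempdir()
  man1 <- write_fixture(sim$stack, sim$truth, d1, config = cfg)
  expect_true(all(file.exists(file.path(d1, man1$file))))
  back <- read_stack(file.path(d1, "stack.tif"))
  expect_identical(back$voxels, sim$stack$voxels)   # integer ADU are exact
  expect_identical(back$pixel_size_um, sim$stack$pixel_size_um)

  sim2 <- simulate_stack(exact_regime_config(11))
  d2 <- withr::local_tempdir()
  man2 <- write_fixture(sim2$stack, sim2$truth, d2)
  dots_csv <- utils::read.csv(file.path(d2, "dots.csv"))
  expect_identical(nrow(dots_csv), nrow(sim2$truth$dots))
  d3 <- withr::local_tempdir()
  man3 <- write_fixture(sim2$stack, sim2$truth, d3)
  expect_identical(man2$md5, man3$md5)
})

test_that("group counts: zero-noise limit, cardinality, and unknown keys", {
  cfg <- group_sim_config(deterministic = TRUE, animal_effect_sd_log = 0)
  d <- simulate_group_counts(cfg)
  arn_di <- d$cells_positive[d$region == "ARN" & d$stage == "diestrus"]
  expect_true(all(arn_di == 12L))                    # round(12.3)
  expect_identical(nrow(d), 5L * 4L * 3L * 3L)

  cfg1 <- group_sim_config(regions = "ARN", n_animals_per_stage = 4L,
                           sections_per_animal = 3L)
  expect_identical(nrow(simulate_group_counts(cfg1)), 60L)

  expect_error(group_sim_config(regions = c("ARN", "NPE")), "known keys")
})

test_that("simulated section counts converge to the configured mean", {
  means <- data.frame(region = "ARN", stage = "lactation", mean = 178.2)
  cfg <- group_sim_config(stages = "lactation", regions = "ARN",
                          n_animals_per_stage = 1L,
                          sections_per_animal = 10000L,
                          mean_cells_per_section = means,
                          nb_dispersion = 5, animal_effect_sd_log = 0,
                          seed = 99L)
  d <- simulate_group_counts(cfg)
  expect_lt(abs(mean(d$cells_positive) - 178.2) / 178.2, 0.02)
})

test_that("group tables are reproducible under a fixed seed", {
  cfg <- group_sim_config(seed = 5L)
  expect_identical(simulate_group_counts(cfg), simulate_group_counts(cfg))
})
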