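render_dot <- function(n, y0, x0, amp, sigma = 1) {
  amp * exp(-(outer(((1:n) - y0)^2, ((1:n) - x0)^2, `+`)) / (2 * sigma^2))
}

test_that("an empty plane yields no candidates", {
  expect_identical(nrow(detect_spots_plane(matrix(0, 64, 64))), 0L)
})

test_that("a 50 ADU Gaussian dot is found within half a pixel", {
  p <- render_dot(64, 31.4, 40.7, amp = 50)
  cand <- detect_spots_plane(p, spot_detect_params(tau_adu = 10))
  expect_identical(nrow(cand), 1L)
  expect_lt(sqrt((cand$y - 31.4)^2 + (cand$x - 40.7)^2), 0.5)
  expect_gte(cand$peak_detail, 10)
})

test_that("a dot scaled below tau over its detail maximum vanishes", {
  unit <- render_dot(64, 31.4, 40.7, amp = 1)
  wmax <- max(oracle_atrous(unit, 3)$detail[[2]])
  p <- render_dot(64, 31.4, 40.7, amp = 0.9 * 10 / wmax)
  expect_identical(nrow(detect_spots_plane(p, spot_detect_params(tau_adu = 10))), 0L)
})

test_that("candidate count is non-increasing in tau", {
  set.seed(21)
  p <- render_dot(96, 20.2, 30.5, 60) + render_dot(96, 70.8, 44.1, 35) +
    matrix(rnorm(96 * 96, 100, 5), 96)
  counts <- vapply(c(1, 3, 5, 8, 10, 15, 25, 60),
                   function(tau) nrow(detect_spots_plane(
                     p, spot_detect_params(tau_adu = tau))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("z-linking chains co-located candidates and keeps singletons", {
  cands <- data.frame(z = c(2L, 3L), y = c(10.0, 10.1), x = c(20.0, 20.0),
                      peak_detail = c(15, 12), area = c(3L, 2L))
  sp <- link_across_z(cands, spot_detect_params(link_radius_px = 2))
  expect_identical(nrow(sp), 1L)
  expect_gte(sp$z, 2); expect_lte(sp$z, 3)
  expect_identical(sp$n_planes, 2L)
  expect_identical(sp$area_px, 5L)
  expect_identical(sp$peak_detail_adu, 15)

  far <- data.frame(z = c(2L, 3L), y = c(10, 40), x = c(20, 60),
                    peak_detail = c(15, 12), area = c(3L, 2L))
  sp2 <- link_across_z(far, spot_detect_params())
  expect_identical(nrow(sp2), 2L)
  expect_true(all(sp2$z == c(2, 3)))
})

test_that("a blank stack yields no spots and high tau empties any stack", {
  blank <- array(100, c(3L, 3L, 48L, 48L))
  s <- image_stack(blank)
  expect_identical(nrow(detect_spots_stack(s, "probe1")), 0L)

  sim <- simulate_stack(exact_regime_config(3))
  det <- detect_spots_stack(sim$stack, "probe1",
                            spot_detect_params(tau_adu = 1e6))
  expect_identical(nrow(det), 0L)
})

test_that("well-separated planted dots are each detected exactly once", {
  sim <- simulate_stack(exact_regime_config(5))
  for (ch in 1:2) {
    det <- detect_spots_stack(sim$stack, paste0("probe", ch))
    td <- sim$truth$dots[sim$truth$dots$channel == ch, ]
    expect_identical(nrow(det), nrow(td))
    expect_identical(match_tp(det, td), nrow(td))
  }
})

test_that("recall is non-decreasing in dot amplitude at fixed noise", {
  recalls <- vapply(c(15, 25, 40, 60), function(amp) {
    cfg <- snr5_config(7, shape = c(4L, 128L, 128L), n_nuclei = 8L)
    cfg$dot_amplitude_adu <- amp   # same seed: same dots and noise draws
    sim <- simulate_stack(cfg)
    det <- detect_spots_stack(sim$stack, "probe1")
    td <- sim$truth$dots[sim$truth$dots$channel == 1, ]
    match_tp(det, td) / nrow(td)
  }, 0)
  expect_true(all(diff(recalls) >= -1e-9))
})

test_that("spot tables round-trip through CSV with the 0-based convention", {
  sim <- simulate_stack(exact_regime_config(4))
  det <- detect_spots_stack(sim$stack, "probe2")
  path <- withr::local_tempfile(fileext = ".csv")
  write_spots_csv(det, path)
  first <- readLines(path, n = 1)
  expect_match(first, "0-based")
  back <- read_spots_csv(path)
  expect_equal(back$y, det$y, tolerance = 1e-12)
  expect_equal(back$roi_label, det$roi_label)
})
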