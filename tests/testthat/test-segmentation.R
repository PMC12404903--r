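seg_fixture <- function(seed, n = 12L) {
  sim_image_config(
    shape_zyx = c(6L, 160L, 160L), n_nuclei = n,
    nucleus_radius_um_range = c(2.8, 3.6),
    dots_per_cell_dist = list(probe1 = list(pi0 = 1, mean = 0, dispersion = 1),
                              probe2 = list(pi0 = 1, mean = 0, dispersion = 1)),
    poisson_noise = FALSE, read_noise_sd_adu = 0, seed = seed)
}

test_that("blank and constant volumes segment to zero labels", {
  expect_identical(n_labels(segment_nuclei(array(0, c(3, 32, 32)))), 0L)
  expect_identical(n_labels(segment_nuclei(array(7, c(3, 32, 32)))), 0L)
})

test_that("well-separated noise-free nuclei are recovered one label each", {
  sim <- simulate_stack(seg_fixture(41))
  seg <- segment_nuclei(sim$stack)
  expect_identical(n_labels(seg), nrow(sim$truth$nuclei))
})

test_that("each recovered nucleus overlaps its truth ellipsoid at IoU >= 0.6", {
  sim <- simulate_stack(seg_fixture(42))
  seg <- segment_nuclei(sim$stack)
  truth <- sim$truth$labels$labels
  for (id in sim$truth$nuclei$id) {
    tmask <- truth == id
    # the matching segmented label is the modal label over the truth mask
    seg_ids <- seg$labels[tmask]
    seg_ids <- seg_ids[seg_ids > 0L]
    expect_gt(length(seg_ids), 0)
    m <- as.integer(names(which.max(table(seg_ids))))
    smask <- seg$labels == m
    iou <- sum(tmask & smask) / sum(tmask | smask)
    expect_gte(iou, 0.6)
  }
})

test_that("label recovery holds across seeds and segmentation is deterministic", {
  for (s in 1:5) {
    sim <- simulate_stack(seg_fixture(s, n = 10L))
    seg1 <- segment_nuclei(sim$stack)
    expect_identical(n_labels(seg1), 10L)
    if (s == 1) {
      seg2 <- segment_nuclei(sim$stack)
      expect_identical(seg1$labels, seg2$labels)
    }
  }
})

test_that("label volumes round-trip through integer TIFF", {
  a <- array(0L, c(3, 12, 12)); a[1, 2:4, 2:4] <- 3L; a[3, 8:10, 6:9] <- 9L
  orig <- label_volume(a)
  path <- withr::local_tempfile(fileext = ".tif")
  write_labels(orig, path)
  back <- load_labels(path)
  # non-contiguous ids {3, 9} come back relabelled {1, 2}, order preserved
  expect_identical(sort(unique(as.vector(back$labels))), c(0L, 1L, 2L))
  expect_identical(attr(back, "relabel_map")$old, c(3L, 9L))
  expect_identical(attr(back, "relabel_map")$new, c(1L, 2L))
  expect_true(all((back$labels == 1L) == (a == 3L)))
  expect_true(all((back$labels == 2L) == (a == 9L)))
  expect_identical(back$provenance, "external")
})

test_that("float label TIFFs and shape mismatches are rejected", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(64), 8), path, bits.per.sample = 32L)
  expect_error(load_labels(path), "non-integer")

  a <- array(1L, c(2, 8, 8))
  path2 <- withr::local_tempfile(fileext = ".tif")
  write_labels(label_volume(a), path2)
  expect_error(load_labels(path2, companion_shape = c(2, 16, 16)),
               "does not match")
})

test_that("size filtering removes labels outside the volume band", {
  a <- array(0L, c(4, 20, 20))
  a[1, 1:5, 1:10] <- 1L                  # 50 voxels
  a[2:3, 3:18, 4:19] <- 2L               # 512 voxels
  x <- label_volume(a)
  expect_identical(filter_labels_by_size(x, 0, Inf)$labels, x$labels)
  out <- filter_labels_by_size(x, 100, Inf)
  expect_identical(sort(unique(as.vector(out$labels))), c(0L, 2L))
  small <- array(0L, c(1, 5, 5)); small[1, 1:2, 1:5] <- 1L  # 10 voxels
  expect_identical(n_labels(filter_labels_by_size(label_volume(small), 11, Inf)), 0L)
  expect_error(filter_labels_by_size(x, 10, 5), "min_vox")
})
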