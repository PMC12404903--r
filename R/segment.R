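#' Nuclei segmentation parameters
#'
#' Tuning for the built-in classical 3D segmenter. Defaults assume the
#' confocal sampling this package targets (~0.55 um/px laterally, 2 um
#' z-steps), where a typical nucleus spans roughly 10 px across and 2-4
#' optical sections.
#'
#' @param smooth_sigma_px lateral Gaussian pre-smoothing sd (pixels); the
#'   axial sd is scaled by the pixel/z-step ratio automatically.
#' @param threshold_method `"otsu"` for a global Otsu threshold on the
#'   smoothed volume, or a number for a fixed threshold (ADU).
#' @param min_volume_vox,max_volume_vox size filter on final labels.
#' @param peak_min_distance_px minimum lateral separation between
#'   watershed seeds (pixels).
#' @param min_seed_distance_px minimum distance-to-background (pixels) a
#'   voxel must have to seed an object; suppresses rim noise.
#' @param edt_cap_px distance transform cap (pixels); must exceed the
#'   largest expected nucleus radius.
#' @return list of class `seg_params`.
#' @export
seg_params <- function(smooth_sigma_px = 1, threshold_method = "otsu",
                       min_volume_vox = 30, max_volume_vox = 10000,
                       peak_min_distance_px = 5,
                       min_seed_distance_px = 2, edt_cap_px = 15) {
  if (smooth_sigma_px < 0) .stopf("smooth_sigma_px must be >= 0")
  if (min_volume_vox > max_volume_vox) .stopf("min_volume_vox must be <= max_volume_vox")
  if (!(identical(threshold_method, "otsu") || is.numeric(threshold_method)))
    .stopf("threshold_method must be \"otsu\" or a fixed numeric value")
  structure(list(smooth_sigma_px = smooth_sigma_px,
                 threshold_method = threshold_method,
                 min_volume_vox = min_volume_vox,
                 max_volume_vox = max_volume_vox,
                 peak_min_distance_px = peak_min_distance_px,
                 min_seed_distance_px = min_seed_distance_px,
                 edt_cap_px = edt_cap_px),
            class = "seg_params")
}

# Seed selection: local maxima of the distance map (box max-filter over
# +-peak_min_distance laterally, +-1 plane axially), then greedy
# non-maximum suppression ordered by (-distance, z, y, x) so the result
# is deterministic. Returns a matrix of (z, y, x) seed coordinates.
.find_seeds <- function(D, fg, min_dist_px, z_scale, min_height) {
  r <- max(1L, as.integer(ceiling(min_dist_px)))
  rz <- max(1L, as.integer(ceiling(min_dist_px / z_scale)))
  mx <- D  # separable box max-filter
  tmp <- mx
  for (dz in seq_len(rz)) tmp <- pmax(tmp, .shift3(mx, dz, 0L, 0L, 0),
                                      .shift3(mx, -dz, 0L, 0L, 0))
  mx <- tmp
  for (dy in seq_len(r)) tmp <- pmax(tmp, .shift3(mx, 0L, dy, 0L, 0),
                                     .shift3(mx, 0L, -dy, 0L, 0))
  mx <- tmp
  for (dx in seq_len(r)) tmp <- pmax(tmp, .shift3(mx, 0L, 0L, dx, 0),
                                     .shift3(mx, 0L, 0L, -dx, 0))
  mx <- tmp
  cand <- which(fg & D >= min_height & D >= mx)
  if (!length(cand)) return(matrix(numeric(0), 0, 3))
  d <- dim(D)
  cz <- ((cand - 1L) %% d[1]) + 1L
  cy <- (((cand - 1L) %/% d[1]) %% d[2]) + 1L
  cx <- ((cand - 1L) %/% (d[1] * d[2])) + 1L
  ord <- order(-D[cand], cz, cy, cx)
  cz <- cz[ord]; cy <- cy[ord]; cx <- cx[ord]
  keep <- logical(length(ord))
  for (i in seq_along(ord)) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    j <- which(keep)
    dd <- sqrt(((cz[i] - cz[j]) * z_scale)^2 + (cy[i] - cy[j])^2 +
                 (cx[i] - cx[j])^2)
    if (all(dd >= min_dist_px)) keep[i] <- TRUE
  }
  cbind(z = cz[keep], y = cy[keep], x = cx[keep])
}

# Seeded watershed by ordered flooding: foreground voxels are visited in
# decreasing distance order and take the smallest positive label among
# their 26-neighbours; repeated until stable. Foreground components never
# reached from any seed get fresh labels (they are typically removed by
# the size filter).
.watershed_flood <- function(D, fg, seeds) {
  d <- dim(D)
  pd <- d + 2L
  pD <- array(-Inf, pd); pfg <- array(FALSE, pd)
  inner <- list(2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L))
  pD[inner[[1]], inner[[2]], inner[[3]]] <- D
  pfg[inner[[1]], inner[[2]], inner[[3]]] <- fg
  lab <- array(0L, pd)
  if (nrow(seeds)) {
    sidx <- (seeds[, 1] + 1L) + seeds[, 2] * pd[1] + seeds[, 3] * pd[1] * pd[2]
    lab[sidx] <- seq_len(nrow(seeds))
  }
  nb <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  nb <- nb[!(nb$dz == 0 & nb$dy == 0 & nb$dx == 0), ]
  deltas <- nb$dz + nb$dy * pd[1] + nb$dx * pd[1] * pd[2]
  vox <- which(pfg)
  vox <- vox[order(-pD[vox], vox)]
  repeat {
    changed <- FALSE
    for (v in vox) {
      if (lab[v] > 0L) next
      nl <- lab[v + deltas]
      nl <- nl[nl > 0L]
      if (length(nl)) { lab[v] <- min(nl); changed <- TRUE }
    }
    vox <- vox[lab[vox] == 0L]
    if (!changed || !length(vox)) break
  }
  if (length(vox)) {   # seedless components
    rem <- array(FALSE, pd); rem[vox] <- TRUE
    comp <- .label_components3(rem[inner[[1]], inner[[2]], inner[[3]]])
    base <- max(lab)
    lab[inner[[1]], inner[[2]], inner[[3]]] <-
      lab[inner[[1]], inner[[2]], inner[[3]]] + ifelse(comp > 0L, comp + base, 0L)
  }
  out <- lab[inner[[1]], inner[[2]], inner[[3]]]
  dim(out) <- d
  out
}

#' Segment nuclei in 3D from the counterstain channel
#'
#' Classical pipeline: anisotropic Gaussian smoothing, global threshold
#' (Otsu or fixed), per-plane hole filling, anisotropy-aware Euclidean
#' distance transform, peak-seeded watershed, and a voxel-volume size
#' filter. Final labels are renumbered `1..K`. Entirely deterministic.
#'
#' The axial anisotropy (z pitch / lateral pixel size) is taken from the
#' stack calibration, or supplied explicitly when `x` is a bare array.
#'
#' @param x an [image_stack] (its `nuclear` channel is used) or a 3D
#'   `(z, y, x)` intensity array.
#' @param params a [seg_params()] object.
#' @param pixel_size_um,z_step_um calibration used when `x` is an array.
#' @return a [label_volume()] with `provenance = "builtin"`. A constant or
#'   all-background input yields an empty label volume, not an error.
#' @export
segment_nuclei <- function(x, params = seg_params(),
                           pixel_size_um = 0.553, z_step_um = 2.0) {
  stopifnot(inherits(params, "seg_params"))
  if (inherits(x, "image_stack")) {
    pixel_size_um <- x$pixel_size_um
    z_step_um <- x$z_step_um
    v <- nuclear_channel(x)
  } else {
    if (!is.array(x) || length(dim(x)) != 3L)
      .stopf("x must be an image_stack or 3D (z, y, x) array")
    v <- x
  }
  z_scale <- z_step_um / pixel_size_um
  sm <- .smooth_volume(v, params$smooth_sigma_px,
                       params$smooth_sigma_px / z_scale)
  if (identical(params$threshold_method, "otsu")) {
    rng <- range(sm)
    if (diff(rng) <= 0)
      return(label_volume(array(0L, dim(v)), provenance = "builtin"))
    flat <- matrix(sm, nrow = dim(v)[1] * dim(v)[2])
    thr <- EBImage::otsu((flat - rng[1]) / diff(rng), range = c(0, 1)) *
      diff(rng) + rng[1]
  } else {
    thr <- params$threshold_method
  }
  fg <- sm > thr
  if (!any(fg))
    return(label_volume(array(0L, dim(v)), provenance = "builtin"))
  for (z in seq_len(dim(v)[1])) {
    m <- fg[z, , ]
    dim(m) <- dim(v)[2:3]
    fg[z, , ] <- EBImage::fillHull(m) > 0
  }
  D <- .edt_capped(fg, z_scale, params$edt_cap_px)
  seeds <- .find_seeds(D, fg, params$peak_min_distance_px, z_scale,
                       params$min_seed_distance_px)
  lab <- .watershed_flood(D, fg, seeds)
  out <- filter_labels_by_size(label_volume(lab, provenance = "builtin"),
                               params$min_volume_vox, params$max_volume_vox)
  label_volume(out$labels, provenance = "builtin", relabel = TRUE)
}
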