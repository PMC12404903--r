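# Internal array helpers shared by the wavelet, segmentation and
# morphology code. All volumes are base-R arrays indexed (z, y, x);
# multichannel stacks are (channel, z, y, x).

# Whole-sample mirror reflection of out-of-range indices into 1..n.
.reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * n - 2L)
  p <- pmin(p, 2L * n - 2L - p)
  p + 1L
}

# 1D convolution of a matrix along one margin with mirror boundary.
# taps[k] multiplies the sample at offset offs[k] along that margin.
.conv_margin <- function(m, taps, offs, margin) {
  n <- dim(m)[margin]
  out <- array(0, dim(m))
  base <- seq_len(n)
  for (k in seq_along(taps)) {
    idx <- .reflect_index(base + offs[k], n)
    if (margin == 1L) out <- out + taps[k] * m[idx, , drop = FALSE]
    else out <- out + taps[k] * m[, idx, drop = FALSE]
  }
  out
}

# Same for a 3D (z, y, x) array along margin 1, 2 or 3.
.conv_margin3 <- function(a, taps, offs, margin) {
  n <- dim(a)[margin]
  out <- array(0, dim(a))
  base <- seq_len(n)
  for (k in seq_along(taps)) {
    idx <- .reflect_index(base + offs[k], n)
    out <- out + taps[k] * switch(margin,
      a[idx, , , drop = FALSE],
      a[, idx, , drop = FALSE],
      a[, , idx, drop = FALSE])
  }
  out
}

.gauss_taps <- function(sigma) {
  if (sigma <= 0) return(list(taps = 1, offs = 0L))
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  offs <- seq.int(-r, r)
  taps <- exp(-offs^2 / (2 * sigma^2))
  list(taps = taps / sum(taps), offs = offs)
}

# Separable anisotropic Gaussian smoothing of a (z, y, x) volume.
.smooth_volume <- function(v, sigma_xy, sigma_z) {
  if (sigma_xy > 0) {
    k <- .gauss_taps(sigma_xy)
    v <- .conv_margin3(v, k$taps, k$offs, 2L)
    v <- .conv_margin3(v, k$taps, k$offs, 3L)
  }
  if (sigma_z > 0 && dim(v)[1] > 1L) {
    k <- .gauss_taps(sigma_z)
    v <- .conv_margin3(v, k$taps, k$offs, 1L)
  }
  v
}

# Shift a (z, y, x) array so out[i,j,k] = a[i+dz, j+dy, k+dx], padding
# out-of-range reads with `fill`.
.shift3 <- function(a, dz, dy, dx, fill) {
  d <- dim(a)
  out <- array(fill, d)
  src <- function(n, s) {
    lo <- max(1L, 1L + s); hi <- min(n, n + s)
    if (lo > hi) NULL else lo:hi
  }
  sz <- src(d[1], dz); sy <- src(d[2], dy); sx <- src(d[3], dx)
  if (is.null(sz) || is.null(sy) || is.null(sx)) return(out)
  out[sz - dz, sy - dy, sx - dx] <- a[sz, sy, sx]
  out
}

# Offsets (dz, dy, dx) with weighted Euclidean norm in (0, cap], sorted by
# increasing distance (ties: dz, dy, dx ascending, so shell processing is
# deterministic). z is weighted by `z_scale` voxel units.
.ball_offsets <- function(cap, z_scale = 1, xy_only = FALSE) {
  rz <- if (xy_only) 0L else as.integer(floor(cap / z_scale))
  r  <- as.integer(floor(cap))
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -rz:rz)
  d <- sqrt((g$dz * z_scale)^2 + g$dy^2 + g$dx^2)
  keep <- d > 0 & d <= cap + 1e-9
  g <- g[keep, , drop = FALSE]; d <- d[keep]
  o <- order(d, g$dz, g$dy, g$dx)
  list(dz = g$dz[o], dy = g$dy[o], dx = g$dx[o], d = d[o])
}

# Capped Euclidean distance-to-background transform of a foreground mask,
# anisotropy-aware (z voxel pitch = z_scale in xy-pixel units). Exact for
# distances <= cap; foreground farther from background than cap gets cap.
# Offsets are scanned in increasing distance order over the shrinking set
# of still-unresolved foreground voxels, so cost is dominated by the few
# deep-interior voxels. Voxels outside the volume count as background.
.edt_capped <- function(fg, z_scale, cap) {
  d <- dim(fg)
  pd <- d + 2L * as.integer(ceiling(cap))
  m <- as.integer(ceiling(cap))
  pbg <- array(TRUE, pd)
  pbg[m + seq_len(d[1]), m + seq_len(d[2]), m + seq_len(d[3])] <- !fg
  idx <- which(!pbg)
  D <- array(0, d)
  if (!length(idx)) return(D)
  off <- .ball_offsets(cap, z_scale)
  deltas <- off$dz + off$dy * pd[1] + off$dx * pd[1] * pd[2]
  dvals <- rep(cap, length(idx))
  open <- seq_along(idx)
  for (i in seq_along(deltas)) {
    if (!length(open)) break
    hit <- pbg[idx[open] + deltas[i]]
    if (any(hit)) {
      dvals[open[hit]] <- off$d[i]
      open <- open[!hit]
    }
  }
  # map padded linear indices back to unpadded coordinates
  iz <- ((idx - 1L) %% pd[1]) + 1L - m
  iy <- (((idx - 1L) %/% pd[1]) %% pd[2]) + 1L - m
  ix <- ((idx - 1L) %/% (pd[1] * pd[2])) + 1L - m
  D[cbind(iz, iy, ix)] <- dvals
  D
}

# Label connected components of a 3D mask (26-connectivity) by flood fill.
# Components are numbered 1..K in order of their smallest linear index.
.label_components3 <- function(mask) {
  d <- dim(mask)
  pd <- d + 2L
  pm <- array(FALSE, pd)
  pm[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  lab <- array(0L, pd)
  nb <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  nb <- nb[!(nb$dz == 0 & nb$dy == 0 & nb$dx == 0), ]
  deltas <- nb$dz + nb$dy * pd[1] + nb$dx * pd[1] * pd[2]
  todo <- which(pm)
  k <- 0L
  visited <- array(FALSE, pd)
  for (v0 in todo) {
    if (visited[v0]) next
    k <- k + 1L
    frontier <- v0
    visited[v0] <- TRUE
    lab[v0] <- k
    while (length(frontier)) {
      cand <- unique(as.vector(outer(frontier, deltas, `+`)))
      cand <- cand[pm[cand] & !visited[cand]]
      if (length(cand)) {
        visited[cand] <- TRUE
        lab[cand] <- k
      }
      frontier <- cand
    }
  }
  out <- lab[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  dim(out) <- d
  out
}

# Round half away from zero (here: nonnegative values, so half-up).
.round_half_up <- function(x) floor(x + 0.5)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
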