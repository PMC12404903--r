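# Independent oracles and shared fixture configs. Each oracle is a
# deliberately naive reimplementation used only to check the package's
# optimised code paths.

# ---- brute-force a trous oracle -------------------------------------------
# Non-separable 2D convolution with the hole-dilated B3 kernel on an
# explicitly mirror-padded matrix (whole-sample reflection).
oracle_atrous <- function(plane, J) {
  taps <- c(1, 4, 6, 4, 1) / 16
  pad_idx <- function(n, P) c(rev(seq_len(P)) + 1L, seq_len(n),
                              n - seq_len(P))
  a <- plane
  detail <- vector("list", J)
  for (j in seq_len(J)) {
    step <- 2L^(j - 1L)
    P <- 2L * step
    K <- outer(taps, taps)                 # 5 x 5 weights at spacing `step`
    M <- a[pad_idx(nrow(a), P), pad_idx(ncol(a), P)]
    s <- matrix(0, nrow(a), ncol(a))
    for (u in 1:5) for (v in 1:5) {
      off_r <- (u - 3L) * step; off_c <- (v - 3L) * step
      s <- s + K[u, v] * M[P + seq_len(nrow(a)) + off_r,
                           P + seq_len(ncol(a)) + off_c]
    }
    detail[[j]] <- a - s
    a <- s
  }
  list(detail = detail, smooth = a)
}

# ---- brute-force nearest-label dilation oracle ----------------------------
# Exhaustive per-voxel distance evaluation, in-plane metric; ties to the
# smallest label id.
oracle_dilate_xy <- function(L, r) {
  out <- L
  d <- dim(L)
  for (z in seq_len(d[1])) {
    pl <- matrix(L[z, , ], d[2], d[3])
    ids <- sort(unique(pl[pl > 0]))
    if (!length(ids)) next
    bg <- which(pl == 0, arr.ind = TRUE)
    if (!nrow(bg)) next
    best_d <- rep(Inf, nrow(bg)); best_l <- rep(0L, nrow(bg))
    for (id in ids) {
      lv <- which(pl == id, arr.ind = TRUE)
      dd <- sqrt(outer(bg[, 1], lv[, 1], `-`)^2 +
                   outer(bg[, 2], lv[, 2], `-`)^2)
      dmin <- apply(dd, 1, min)
      upd <- dmin < best_d - 1e-12
      best_d[upd] <- dmin[upd]; best_l[upd] <- id
    }
    sel <- best_d <= r + 1e-9
    if (any(sel)) pl[bg[sel, , drop = FALSE]] <- best_l[sel]
    out[z, , ] <- pl
  }
  out
}

# ---- exact Kruskal-Wallis permutation oracle ------------------------------
# Full enumeration of group assignments; the statistic per assignment
# comes from stats::kruskal.test, independent of the package. Reports the
# mid-p value (P(H > h) + P(H = h)/2), the standard convention when a
# discrete exact null is compared with a continuous approximation.
oracle_perm_p <- function(groups) {
  pooled <- unlist(groups)
  sizes <- vapply(groups, length, 0L)
  H_obs <- unname(stats::kruskal.test(
    pooled, factor(rep(seq_along(groups), sizes)))$statistic)
  gen <- function(avail, sizes) {
    if (length(sizes) == 1L) return(list(list(avail)))
    out <- list()
    for (f in utils::combn(avail, sizes[1], simplify = FALSE))
      for (rest in gen(setdiff(avail, f), sizes[-1]))
        out[[length(out) + 1L]] <- c(list(f), rest)
    out
  }
  parts <- gen(seq_along(pooled), sizes)
  Hs <- vapply(parts, function(p) {
    lab <- integer(length(pooled))
    for (i in seq_along(p)) lab[p[[i]]] <- i
    unname(stats::kruskal.test(pooled, factor(lab))$statistic)
  }, 0)
  mean(Hs > H_obs + 1e-9) + 0.5 * mean(abs(Hs - H_obs) <= 1e-9)
}

# ---- greedy spot-to-truth matching ----------------------------------------
# True positives at a lateral match radius and an axial tolerance;
# closest pairs matched first, each spot/dot used once.
match_tp <- function(det, td, radius = 2, zmax = 1.5) {
  if (!nrow(det) || !nrow(td)) return(0L)
  pairs <- expand.grid(i = seq_len(nrow(td)), j = seq_len(nrow(det)))
  dd <- sqrt((td$y[pairs$i] - det$y[pairs$j])^2 +
               (td$x[pairs$i] - det$x[pairs$j])^2)
  keep <- dd <= radius & abs(td$z[pairs$i] - det$z[pairs$j]) <= zmax
  pairs <- pairs[keep, , drop = FALSE]; dd <- dd[keep]
  ord <- order(dd)
  used_i <- logical(nrow(td)); used_j <- logical(nrow(det))
  tp <- 0L
  for (k in ord) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (used_i[i] || used_j[j]) next
    used_i[i] <- TRUE; used_j[j] <- TRUE
    tp <- tp + 1L
  }
  tp
}

detection_f1 <- function(det, td, radius = 2, zmax = 1.5) {
  tp <- match_tp(det, td, radius, zmax)
  prec <- tp / max(nrow(det), 1L)
  rec <- tp / max(nrow(td), 1L)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# ---- shared fixture configs -----------------------------------------------
# Noise-free, well-separated regime for exact count recovery.
exact_regime_config <- function(seed) {
  sim_image_config(
    shape_zyx = c(4L, 96L, 96L), n_nuclei = 7L,
    nucleus_radius_um_range = c(2.8, 3.4),
    dots_per_cell_dist = list(
      probe1 = list(pi0 = 0.25, mean = 3, dispersion = 5),
      probe2 = list(pi0 = 0.25, mean = 3, dispersion = 5)),
    poisson_noise = FALSE, read_noise_sd_adu = 0,
    min_dot_separation_px = 7, seed = seed)
}

# Study-noise regime: ~200 dots per channel at SNR 5 (amplitude 50 ADU
# over Poisson background 100 plus 2 ADU read noise).
snr5_config <- function(seed, shape = c(6L, 256L, 256L), n_nuclei = 30L) {
  sim_image_config(
    shape_zyx = shape, n_nuclei = n_nuclei,
    nucleus_radius_um_range = c(2.8, 3.4),
    dots_per_cell_dist = list(
      probe1 = list(pi0 = 0, mean = 6.4, dispersion = 1e6),
      probe2 = list(pi0 = 0, mean = 6.4, dispersion = 1e6)),
    dot_amplitude_adu = 50, background_adu = 100, read_noise_sd_adu = 2,
    poisson_noise = TRUE, min_dot_separation_px = 5, seed = seed)
}

truth_counts_wide <- function(truth) {
  tc <- truth$true_counts
  w <- merge(tc[tc$channel == 1, c("cell_id", "count")],
             tc[tc$channel == 2, c("cell_id", "count")],
             by = "cell_id", suffixes = c("_p1", "_p2"))
  w[order(w$cell_id), ]
}

quantify_stack <- function(sim, params = spot_detect_params()) {
  rois <- dilate_labels(sim$truth$labels, dilation_params(2))
  sp <- rbind(assign_spots(detect_spots_stack(sim$stack, "probe1", params), rois),
              assign_spots(detect_spots_stack(sim$stack, "probe2", params), rois))
  tabulate_counts(sp, rois)
}
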