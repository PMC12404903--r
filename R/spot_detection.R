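#' Spot detection parameters
#'
#' Controls the wavelet-based dot detector. Detection thresholds the
#' detail coefficients at `tau_adu` analog-digital units on every scale in
#' `scales_used` (the suprathreshold mask is the AND over those scales),
#' keeps 8-connected mask components of at least `min_mask_px` pixels, and
#' links per-plane candidates across z into single 3D spots.
#'
#' @param tau_adu hard threshold on wavelet detail coefficients (ADU).
#' @param scales_used integer scales whose detail planes enter the mask.
#'   The default (scale 2 alone) matches diffraction-limited dots 1-2 px
#'   wide at ~0.55 um/pixel sampling, whose detail energy concentrates at
#'   that scale; requiring coarser scales to clear the same threshold
#'   would reject genuine single-molecule dots.
#' @param J total number of wavelet scales computed.
#' @param link_radius_px maximum lateral displacement (pixels) when
#'   chaining candidates in adjacent z-planes into one spot.
#' @param link_z_gap maximum number of skipped planes inside a chain.
#' @param min_mask_px minimum suprathreshold component area (pixels).
#'   At the default `tau_adu` of 10 ADU — about five times the detail-plane
#'   noise under typical confocal shot noise — single-pixel hits are
#'   already overwhelmingly genuine, so the default is 1; raise it when
#'   running with a lower threshold.
#' @return list of class `spot_detect_params`.
#' @export
spot_detect_params <- function(tau_adu = 10, scales_used = 2L, J = 3L,
                               link_radius_px = 2, link_z_gap = 0L,
                               min_mask_px = 1L) {
  J <- as.integer(J); scales_used <- as.integer(scales_used)
  if (tau_adu < 0) .stopf("tau_adu must be >= 0")
  if (length(scales_used) < 1L || any(scales_used < 1L) || any(scales_used > J))
    .stopf("scales_used must be a nonempty subset of 1..J")
  if (link_radius_px < 0 || link_z_gap < 0 || min_mask_px < 1L)
    .stopf("link parameters must be >= 0 and min_mask_px >= 1")
  structure(list(tau_adu = tau_adu, scales_used = scales_used, J = J,
                 link_radius_px = link_radius_px,
                 link_z_gap = as.integer(link_z_gap),
                 min_mask_px = as.integer(min_mask_px)),
            class = "spot_detect_params")
}

# 8-connected component labelling of a logical matrix; components numbered
# in order of smallest linear (column-major) index.
.label_components2 <- function(mask) {
  d <- dim(mask)
  pd <- d + 2L
  pm <- matrix(FALSE, pd[1], pd[2])
  pm[2:(d[1] + 1L), 2:(d[2] + 1L)] <- mask
  lab <- matrix(0L, pd[1], pd[2])
  deltas <- c(-1L - pd[1], -pd[1], 1L - pd[1], -1L, 1L,
              pd[1] - 1L, pd[1], pd[1] + 1L)
  k <- 0L
  for (v0 in which(pm & lab == 0L)) {
    if (lab[v0] > 0L) next
    k <- k + 1L
    frontier <- v0
    lab[v0] <- k
    while (length(frontier)) {
      cand <- unique(as.vector(outer(frontier, deltas, `+`)))
      cand <- cand[pm[cand] & lab[cand] == 0L]
      lab[cand] <- k
      frontier <- cand
    }
  }
  lab[2:(d[1] + 1L), 2:(d[2] + 1L)]
}

#' Detect dot candidates in a single image plane
#'
#' Decomposes the plane with [atrous_decompose()], thresholds the detail
#' coefficients at `tau_adu` on each scale in `scales_used`, and reports
#' every 8-connected suprathreshold component of area >= `min_mask_px` as
#' a candidate at its detail-intensity-weighted centroid.
#'
#' @param plane 2D numeric matrix.
#' @param params a [spot_detect_params()] object.
#' @return data.frame with columns `y`, `x` (1-based, sub-pixel),
#'   `peak_detail` (maximum detail coefficient in the component, ADU) and
#'   `area` (component pixel count), ordered by (`y`, `x`).
#' @export
detect_spots_plane <- function(plane, params = spot_detect_params()) {
  stopifnot(inherits(params, "spot_detect_params"))
  w <- atrous_decompose(plane, params$J)
  used <- w$detail[params$scales_used]
  mask <- Reduce(`&`, lapply(used, function(W) W >= params$tau_adu))
  empty <- data.frame(y = numeric(0), x = numeric(0),
                      peak_detail = numeric(0), area = integer(0))
  if (!any(mask)) return(empty)
  lab <- .label_components2(mask)
  wsum <- Reduce(`+`, used)
  wmax <- Reduce(pmax, used)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  area <- tabulate(comp)
  keep <- which(area >= params$min_mask_px)
  if (!length(keep)) return(empty)
  yy <- ((idx - 1L) %% nrow(plane)) + 1L
  xx <- ((idx - 1L) %/% nrow(plane)) + 1L
  wt <- pmax(wsum[idx], 1e-12)
  num_y <- vapply(keep, function(k) sum((wt * yy)[comp == k]), 0)
  num_x <- vapply(keep, function(k) sum((wt * xx)[comp == k]), 0)
  den   <- vapply(keep, function(k) sum(wt[comp == k]), 0)
  pk    <- vapply(keep, function(k) max(wmax[idx][comp == k]), 0)
  out <- data.frame(y = num_y / den, x = num_x / den,
                    peak_detail = pk, area = area[keep])
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Link per-plane dot candidates across z into 3D spots
#'
#' Greedy nearest-neighbour chaining: walking up the stack, a candidate
#' joins the open chain whose last member lies within `link_radius_px`
#' laterally and at most `link_z_gap + 1` planes below; the closest pair
#' is linked first and each candidate is used at most once (ties broken by
#' chain age, then candidate (y, x) order). Each chain emits one spot at
#' the detail-weighted mean position of its members.
#'
#' @param per_plane data.frame of candidates with columns `z` (integer
#'   plane index), `y`, `x`, `peak_detail`, `area` (as produced by
#'   [detect_spots_plane()] plus a `z` column).
#' @param params a [spot_detect_params()] object.
#' @return data.frame of spots: `z`, `y`, `x` (sub-voxel, 1-based),
#'   `peak_detail_adu` (max over members), `area_px` (summed footprint),
#'   `n_planes`, `roi_label` (0, unassigned).
#' @export
link_across_z <- function(per_plane, params = spot_detect_params()) {
  stopifnot(inherits(params, "spot_detect_params"))
  cols <- c("z", "y", "x", "peak_detail", "area")
  if (!all(cols %in% names(per_plane))) .stopf("per_plane needs columns %s",
                                               paste(cols, collapse = ", "))
  n <- nrow(per_plane)
  if (n == 0L)
    return(data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                      peak_detail_adu = numeric(0), area_px = integer(0),
                      n_planes = integer(0), roi_label = integer(0)))
  pp <- per_plane[order(per_plane$z, per_plane$y, per_plane$x), , drop = FALSE]
  chain_id <- integer(n)            # chain index per candidate
  last_of <- integer(0)             # row index of each chain's newest member
  n_chain <- 0L
  for (z in sort(unique(pp$z))) {
    rows <- which(pp$z == z)
    open <- which(pp$z[last_of] >= z - 1L - params$link_z_gap &
                    pp$z[last_of] < z)
    if (length(open) && length(rows)) {
      pairs <- expand.grid(ci = open, ri = rows)
      dist <- sqrt((pp$y[pairs$ri] - pp$y[last_of[pairs$ci]])^2 +
                     (pp$x[pairs$ri] - pp$x[last_of[pairs$ci]])^2)
      ok <- dist <= params$link_radius_px
      pairs <- pairs[ok, , drop = FALSE]; dist <- dist[ok]
      ord <- order(dist, pairs$ci, pairs$ri)
      used_c <- logical(n_chain); used_r <- logical(n)
      for (i in ord) {
        ci <- pairs$ci[i]; ri <- pairs$ri[i]
        if (used_c[ci] || used_r[ri]) next
        used_c[ci] <- TRUE; used_r[ri] <- TRUE
        chain_id[ri] <- ci
        last_of[ci] <- ri
      }
    }
    for (ri in rows) {
      if (chain_id[ri] == 0L) {
        n_chain <- n_chain + 1L
        chain_id[ri] <- n_chain
        last_of[n_chain] <- ri
      }
    }
  }
  agg <- function(f) vapply(seq_len(n_chain), function(c) {
    m <- chain_id == c
    f(pp[m, , drop = FALSE])
  }, 0)
  wmean <- function(df, col) sum(df[[col]] * df$peak_detail) / sum(df$peak_detail)
  out <- data.frame(
    z = agg(function(df) wmean(df, "z")),
    y = agg(function(df) wmean(df, "y")),
    x = agg(function(df) wmean(df, "x")),
    peak_detail_adu = agg(function(df) max(df$peak_detail)),
    area_px = as.integer(agg(function(df) sum(df$area))),
    n_planes = as.integer(agg(nrow)),
    roi_label = 0L)
  out <- out[order(out$z, out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect spots in one channel of a 3D stack
#'
#' Runs [detect_spots_plane()] on every z-plane of the requested channel
#' and merges per-plane candidates with [link_across_z()]. Deterministic:
#' identical input gives identical output.
#'
#' @param x an [image_stack], or a 3D `(z, y, x)` numeric array.
#' @param channel channel index or role name; ignored when `x` is an array.
#' @param params a [spot_detect_params()] object.
#' @return data.frame of spots with a leading `channel` column (integer
#'   index when known, `NA` for bare arrays) plus the columns of
#'   [link_across_z()].
#' @export
detect_spots_stack <- function(x, channel = NULL,
                               params = spot_detect_params()) {
  if (inherits(x, "image_stack")) {
    ch_idx <- if (is.character(channel)) x$channel_roles[[channel]] else channel
    if (is.null(ch_idx)) .stopf("channel is required for an image_stack")
    vol <- stack_channel(x, ch_idx)
  } else {
    if (!is.array(x) || length(dim(x)) != 3L)
      .stopf("x must be an image_stack or a 3D (z, y, x) array")
    vol <- x
    ch_idx <- if (is.null(channel)) NA_integer_ else as.integer(channel)
  }
  cands <- lapply(seq_len(dim(vol)[1]), function(z) {
    m <- vol[z, , ]
    dim(m) <- dim(vol)[2:3]
    df <- detect_spots_plane(m, params)
    if (nrow(df)) df$z <- z
    df
  })
  cands <- do.call(rbind, cands[vapply(cands, nrow, 0L) > 0])
  if (is.null(cands)) cands <- data.frame(z = numeric(0), y = numeric(0),
                                          x = numeric(0),
                                          peak_detail = numeric(0),
                                          area = integer(0))
  spots <- link_across_z(cands, params)
  cbind(channel = rep(as.integer(ch_idx), nrow(spots)), spots)
}

#' Write and read spot tables as CSV
#'
#' Coordinates are stored 0-based (voxel units) in the file, converted to
#' this package's 1-based convention on read; the convention is recorded
#' in a `#` comment line at the top of the file.
#'
#' @param spots spot data.frame ([detect_spots_stack()] output).
#' @param path CSV path.
#' @return `write_spots_csv` returns `path` invisibly; `read_spots_csv`
#'   returns the spot data.frame.
#' @export
write_spots_csv <- function(spots, path) {
  out <- spots[, c("channel", "z", "y", "x", "peak_detail_adu",
                   "area_px", "roi_label")]
  out$z <- out$z - 1; out$y <- out$y - 1; out$x <- out$x - 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# z,y,x are 0-based voxel coordinates", con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spots_csv
#' @export
read_spots_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  df$z <- df$z + 1; df$y <- df$y + 1; df$x <- df$x + 1
  df
}
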