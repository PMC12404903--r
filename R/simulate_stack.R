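#' Configuration for the confocal stack simulator
#'
#' Defaults emulate the imaging geometry of the quantified experiment:
#' 512 x 512 px fields at 0.553 um/pixel, 2 um z-steps through a 16 um
#' section (8 planes), Hoechst-like nuclei rendered as soft-edged
#' spheres (in physical units; ellipsoids in voxel units because of the
#' axial anisotropy), and RNAscope dots rendered as anisotropic Gaussians
#' with per-cell counts drawn from a zero-inflated negative binomial.
#'
#' @param shape_zyx integer `(z, y, x)` voxel counts.
#' @param pixel_size_um lateral calibration (um/pixel).
#' @param z_step_um axial step (um).
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_radius_um_range `(min, max)` nuclear radius in um.
#' @param nucleus_intensity_adu mean counterstain amplitude (ADU).
#' @param dots_per_cell_dist per-channel zero-inflated negative binomial
#'   spec: named list `probe1`/`probe2`, each `list(pi0, mean, dispersion)`
#'   where `pi0` is the non-expressing fraction and `mean`/`dispersion`
#'   parameterize the NB count of expressing cells.
#' @param dot_amplitude_adu mean dot peak amplitude above background (ADU).
#' @param dot_sigma_px lateral Gaussian sd of a rendered dot (pixels).
#' @param dot_sigma_z_slices axial sd in z-slice units.
#' @param background_adu constant offset (ADU).
#' @param read_noise_sd_adu additive Gaussian read noise sd (ADU).
#' @param poisson_noise apply Poisson (shot) noise before read noise.
#' @param extracellular_frac fraction of all dots placed outside any cell
#'   ROI, exercising background assignment.
#' @param dilation_radius_px perinuclear margin within which intracellular
#'   dots are placed (matches the quantification dilation).
#' @param min_dot_separation_px if > 0, enforce at least this lateral
#'   distance between dots of the same channel (used for exact-recovery
#'   regimes; 0 disables).
#' @param dot_jitter_px half-width of the uniform sub-voxel offset applied
#'   to dot centres laterally (kept below 0.5 so the nearest voxel of a
#'   dot is its sampled footprint voxel).
#' @param quantize_adu round final voxel values to whole ADU, emulating
#'   the detector's analog-to-digital conversion (default); disable for
#'   tests of the continuous rendering model.
#' @param seed integer RNG seed; identical config + seed gives
#'   bit-identical output.
#' @return list of class `sim_image_config`.
#' @export
sim_image_config <- function(shape_zyx = c(8L, 512L, 512L),
                             pixel_size_um = 0.553, z_step_um = 2.0,
                             n_nuclei = 30L,
                             nucleus_radius_um_range = c(3, 5),
                             nucleus_intensity_adu = 2000,
                             dots_per_cell_dist = list(
                               probe1 = list(pi0 = 0.5, mean = 15, dispersion = 2),
                               probe2 = list(pi0 = 0.5, mean = 15, dispersion = 2)),
                             dot_amplitude_adu = 50,
                             dot_sigma_px = 1.0, dot_sigma_z_slices = 0.5,
                             background_adu = 100, read_noise_sd_adu = 2,
                             poisson_noise = TRUE,
                             extracellular_frac = 0.05,
                             dilation_radius_px = 2,
                             min_dot_separation_px = 0,
                             dot_jitter_px = 0.35,
                             quantize_adu = TRUE,
                             seed = 1L) {
  if (any(shape_zyx < 1)) .stopf("all dimensions must be > 0")
  if (pixel_size_um <= 0 || z_step_um <= 0) .stopf("calibration must be positive")
  if (n_nuclei < 0) .stopf("n_nuclei must be >= 0")
  if (nucleus_radius_um_range[1] > nucleus_radius_um_range[2])
    .stopf("nucleus radius range must have min <= max")
  for (ch in c("probe1", "probe2")) {
    p <- dots_per_cell_dist[[ch]]
    if (is.null(p)) .stopf("dots_per_cell_dist must define %s", ch)
    if (p$pi0 < 0 || p$pi0 > 1) .stopf("pi0 must be in [0, 1]")
    if (p$dispersion <= 0) .stopf("dispersion must be > 0")
    if (p$mean < 0) .stopf("dot count mean must be >= 0")
  }
  if (dot_amplitude_adu < 0 || nucleus_intensity_adu < 0 || background_adu < 0)
    .stopf("amplitudes must be >= 0")
  if (extracellular_frac < 0 || extracellular_frac >= 1)
    .stopf("extracellular_frac must be in [0, 1)")
  if (dot_jitter_px < 0 || dot_jitter_px >= 0.5)
    .stopf("dot_jitter_px must be in [0, 0.5)")
  structure(as.list(environment()), class = "sim_image_config")
}

# Rasterize nuclei as spheres of radius r um (anisotropic in voxels).
# Returns integer truth labels and the rendered soft-edged intensity.
.render_nuclei <- function(cfg, nuc) {
  d <- cfg$shape_zyx
  lab <- array(0L, d)
  img <- array(0, d)
  if (nrow(nuc) == 0) return(list(labels = lab, image = img))
  for (i in seq_len(nrow(nuc))) {
    r_um <- nuc$r_um[i]
    rz <- r_um / cfg$z_step_um; rxy <- r_um / cfg$pixel_size_um
    zr <- max(1L, floor(nuc$cz[i] - rz - 1)):min(d[1], ceiling(nuc$cz[i] + rz + 1))
    yr <- max(1L, floor(nuc$cy[i] - rxy - 2)):min(d[2], ceiling(nuc$cy[i] + rxy + 2))
    xr <- max(1L, floor(nuc$cx[i] - rxy - 2)):min(d[3], ceiling(nuc$cx[i] + rxy + 2))
    rho <- sqrt(outer(outer(((zr - nuc$cz[i]) / rz)^2,
                            ((yr - nuc$cy[i]) / rxy)^2, `+`),
                      ((xr - nuc$cx[i]) / rxy)^2, `+`))
    lab[zr, yr, xr][rho <= 1] <- i
    img[zr, yr, xr] <- img[zr, yr, xr] +
      cfg$nucleus_intensity_adu / (1 + exp((rho - 1) / 0.08))
  }
  list(labels = lab, image = img)
}

# Draw a zero-inflated negative binomial count.
.rzinb <- function(n, pi0, mean, dispersion) {
  expr <- stats::runif(n) >= pi0
  k <- integer(n)
  if (any(expr))
    k[expr] <- stats::rnbinom(sum(expr), size = dispersion, mu = mean)
  k
}

#' Simulate a confocal-like 3-channel z-stack with ground truth
#'
#' Places non-overlapping nuclei (rejection sampling on centre positions;
#' physical centre separation at least the sum of radii), renders the
#' counterstain channel, draws per-cell dot counts for both probe
#' channels from the configured zero-inflated negative binomial, places
#' each intracellular dot at a uniformly sampled voxel of its cell's
#' dilated footprint (plus a bounded sub-voxel offset), adds a configured
#' fraction of extracellular dots on background voxels, renders all dots
#' as anisotropic Gaussians, and applies Poisson then Gaussian read noise.
#'
#' @param config a [sim_image_config()].
#' @return list with elements `stack` (an [image_stack]) and `truth`, a
#'   `ground_truth` list holding `nuclei` (id, centre, voxel radii),
#'   `dots` (channel, cell_id with 0 = extracellular, sub-voxel z/y/x),
#'   `true_counts` (cell_id x channel tally), `labels` (truth nucleus
#'   [label_volume]) and `dilated` (its dilation by `dilation_radius_px`).
#' @export
simulate_stack <- function(config = sim_image_config()) {
  stopifnot(inherits(config, "sim_image_config"))
  withr::with_seed(config$seed, .simulate_stack_impl(config))
}

.simulate_stack_impl <- function(cfg) {
  d <- cfg$shape_zyx
  # --- place nuclei ---
  nuc <- data.frame(id = integer(0), cz = numeric(0), cy = numeric(0),
                    cx = numeric(0), r_um = numeric(0))
  if (cfg$n_nuclei > 0) {
    max_try <- 200L * cfg$n_nuclei
    tries <- 0L
    while (nrow(nuc) < cfg$n_nuclei && tries < max_try) {
      tries <- tries + 1L
      r_um <- stats::runif(1, cfg$nucleus_radius_um_range[1],
                           cfg$nucleus_radius_um_range[2])
      rz <- r_um / cfg$z_step_um; rxy <- r_um / cfg$pixel_size_um
      # lateral margin keeps the dilated footprint and rendered dots in-field
      marg <- rxy + cfg$dilation_radius_px + 3
      if (2 * marg >= min(d[2], d[3]))
        .stopf("nucleus radius %.2f um does not fit the field", r_um)
      z_lo <- 1 + rz * 0.5; z_hi <- d[1] - rz * 0.5
      cz <- if (z_hi <= z_lo) (1 + d[1]) / 2 else stats::runif(1, z_lo, z_hi)
      cy <- stats::runif(1, 1 + marg, d[2] - marg)
      cx <- stats::runif(1, 1 + marg, d[3] - marg)
      ok <- TRUE
      if (nrow(nuc)) {
        sep <- sqrt(((cz - nuc$cz) * cfg$z_step_um)^2 +
                      ((cy - nuc$cy) * cfg$pixel_size_um)^2 +
                      ((cx - nuc$cx) * cfg$pixel_size_um)^2)
        ok <- all(sep >= r_um + nuc$r_um)
      }
      if (ok) nuc[nrow(nuc) + 1L, ] <- list(nrow(nuc) + 1L, cz, cy, cx, r_um)
    }
    if (nrow(nuc) < cfg$n_nuclei)
      .stopf("could only place %d of %d nuclei without overlap; reduce n_nuclei or radii",
             nrow(nuc), cfg$n_nuclei)
  }
  rn <- .render_nuclei(cfg, nuc)
  truth_labels <- label_volume(rn$labels, provenance = "builtin")
  dilated <- dilate_labels(truth_labels,
                           dilation_params(radius_px = cfg$dilation_radius_px))

  # --- draw counts and place dots ---
  channels <- c(probe1 = 1L, probe2 = 2L)
  dl <- dilated$labels
  cell_vox <- if (nrow(nuc)) split(which(dl > 0L), dl[dl > 0L]) else list()
  bg_vox <- which(dl == 0L)
  dots <- list()
  for (ch_name in names(channels)) {
    ch <- channels[[ch_name]]
    spec <- cfg$dots_per_cell_dist[[ch_name]]
    k <- if (nrow(nuc)) .rzinb(nrow(nuc), spec$pi0, spec$mean, spec$dispersion)
         else integer(0)
    placed_yx <- matrix(numeric(0), 0, 2)
    # When a minimum dot separation is requested (the well-separated
    # validation regime), a dot that cannot be placed after bounded
    # retries is dropped rather than packed too densely; true_counts
    # always tallies the dots actually in the scene.
    place_one <- function(vox_pool) {
      for (try in 1:500) {
        v <- vox_pool[sample.int(length(vox_pool), 1L)]
        vz <- ((v - 1L) %% d[1]) + 1L
        vy <- (((v - 1L) %/% d[1]) %% d[2]) + 1L
        vx <- ((v - 1L) %/% (d[1] * d[2])) + 1L
        py <- vy + stats::runif(1, -cfg$dot_jitter_px, cfg$dot_jitter_px)
        px <- vx + stats::runif(1, -cfg$dot_jitter_px, cfg$dot_jitter_px)
        pz <- vz + stats::runif(1, -0.25, 0.25)
        sep_ok <- cfg$min_dot_separation_px <= 0 || nrow(placed_yx) == 0 ||
          all(sqrt((placed_yx[, 1] - py)^2 + (placed_yx[, 2] - px)^2) >=
                cfg$min_dot_separation_px)
        if (sep_ok) {
          placed_yx <<- rbind(placed_yx, c(py, px))
          return(c(pz, py, px))
        }
      }
      NULL
    }
    n_intra <- 0L
    for (i in seq_len(nrow(nuc))) {
      if (k[i] == 0L || length(cell_vox[[as.character(i)]]) == 0L) next
      for (m in seq_len(k[i])) {
        p <- place_one(cell_vox[[as.character(i)]])
        if (is.null(p)) next
        n_intra <- n_intra + 1L
        dots[[length(dots) + 1L]] <-
          data.frame(channel = ch, cell_id = i, z = p[1], y = p[2], x = p[3])
      }
    }
    n_extra <- .round_half_up(n_intra * cfg$extracellular_frac /
                                (1 - cfg$extracellular_frac))
    if (n_extra > 0 && length(bg_vox)) {
      for (m in seq_len(n_extra)) {
        p <- place_one(bg_vox)
        if (!is.null(p))
          dots[[length(dots) + 1L]] <-
            data.frame(channel = ch, cell_id = 0L, z = p[1], y = p[2], x = p[3])
      }
    }
  }
  dots <- if (length(dots)) do.call(rbind, dots)
          else data.frame(channel = integer(0), cell_id = integer(0),
                          z = numeric(0), y = numeric(0), x = numeric(0))
  true_counts <- expand.grid(cell_id = nuc$id, channel = channels,
                             KEEP.OUT.ATTRS = FALSE)
  true_counts$count <- if (nrow(true_counts))
    mapply(function(id, ch) sum(dots$cell_id == id & dots$channel == ch),
           true_counts$cell_id, true_counts$channel) else integer(0)
  true_counts <- true_counts[order(true_counts$channel, true_counts$cell_id), ]
  rownames(true_counts) <- NULL

  # --- render ---
  v <- array(cfg$background_adu, c(3L, d))
  v[3, , , ] <- v[3, , , ] + rn$image
  if (nrow(dots)) {
    rx <- ceiling(4 * cfg$dot_sigma_px)
    rz <- max(1L, ceiling(3 * cfg$dot_sigma_z_slices))
    for (i in seq_len(nrow(dots))) {
      zr <- max(1L, floor(dots$z[i] - rz)):min(d[1], ceiling(dots$z[i] + rz))
      yr <- max(1L, floor(dots$y[i] - rx)):min(d[2], ceiling(dots$y[i] + rx))
      xr <- max(1L, floor(dots$x[i] - rx)):min(d[3], ceiling(dots$x[i] + rx))
      g <- cfg$dot_amplitude_adu *
        exp(-outer(outer(((zr - dots$z[i]) / cfg$dot_sigma_z_slices)^2,
                         ((yr - dots$y[i]) / cfg$dot_sigma_px)^2, `+`),
                   ((xr - dots$x[i]) / cfg$dot_sigma_px)^2, `+`) / 2)
      ch <- dots$channel[i]
      v[ch, zr, yr, xr] <- v[ch, zr, yr, xr] + g
    }
  }
  if (cfg$poisson_noise) v[] <- stats::rpois(length(v), lambda = v)
  if (cfg$read_noise_sd_adu > 0)
    v <- v + stats::rnorm(length(v), sd = cfg$read_noise_sd_adu)
  if (isTRUE(cfg$quantize_adu)) v <- round(v)
  v[v < 0] <- 0
  stack <- image_stack(v, pixel_size_um = cfg$pixel_size_um,
                       z_step_um = cfg$z_step_um)
  nuclei <- data.frame(id = nuc$id, cz = nuc$cz, cy = nuc$cy, cx = nuc$cx,
                       rz = nuc$r_um / cfg$z_step_um,
                       ry = nuc$r_um / cfg$pixel_size_um,
                       rx = nuc$r_um / cfg$pixel_size_um)
  truth <- structure(list(nuclei = nuclei, dots = dots,
                          true_counts = true_counts,
                          labels = truth_labels, dilated = dilated),
                     class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Write a simulated stack and its ground truth as a reusable fixture
#'
#' Writes the stack TIFF (+ sidecar), truth nucleus labels, `nuclei.csv`
#' (`id,cz,cy,cx,rz,ry,rx`, 0-based centres), `dots.csv`
#' (`channel,cell_id,z,y,x`, 0-based), `true_counts.csv`, and an echo of
#' the generating configuration. Returns (and writes) a manifest of file
#' paths with MD5 checksums; identical inputs produce identical checksums.
#'
#' @param stack an [image_stack].
#' @param truth the matching `ground_truth`.
#' @param out_dir output directory (created if needed).
#' @param config optional [sim_image_config()] to echo alongside.
#' @return data.frame manifest (`file`, `md5`), invisibly.
#' @export
write_fixture <- function(stack, truth, out_dir, config = NULL) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      .stopf("cannot create directory %s", out_dir)
  p <- function(f) file.path(out_dir, f)
  write_stack(stack, p("stack.tif"))
  write_labels(truth$labels, p("labels.tif"),
               pixel_size_um = stack$pixel_size_um,
               z_step_um = stack$z_step_um)
  nz <- truth$nuclei
  nz$cz <- nz$cz - 1; nz$cy <- nz$cy - 1; nz$cx <- nz$cx - 1
  utils::write.csv(nz, p("nuclei.csv"), row.names = FALSE)
  dd <- truth$dots
  dd$z <- dd$z - 1; dd$y <- dd$y - 1; dd$x <- dd$x - 1
  utils::write.csv(dd, p("dots.csv"), row.names = FALSE)
  utils::write.csv(truth$true_counts, p("true_counts.csv"), row.names = FALSE)
  files <- c("stack.tif", "stack.tif.json", "labels.tif", "labels.tif.json",
             "nuclei.csv", "dots.csv", "true_counts.csv")
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), p("config.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, "config.json")
  }
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(vapply(files, p, ""))))
  utils::write.csv(manifest, p("manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
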