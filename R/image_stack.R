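#' Multichannel confocal z-stack container
#'
#' An `image_stack` holds a 3-channel 3D voxel volume in detector units
#' (ADU) together with its physical calibration. Voxels are indexed
#' `(channel, z, y, x)`. Exactly one channel must carry the `"nuclear"`
#' role (the counterstain used for segmentation); the probe channels carry
#' roles `"probe1"` and `"probe2"`.
#'
#' @param voxels numeric array with dim `(channel, z, y, x)`, values >= 0.
#' @param pixel_size_um lateral calibration, micrometres per pixel.
#' @param z_step_um axial step between optical sections, micrometres.
#' @param channel_roles named integer vector mapping roles
#'   (`probe1`, `probe2`, `nuclear`) to channel indices.
#' @return An object of class `image_stack`.
#' @examples
#' v <- array(100, c(3, 2, 16, 16))
#' s <- image_stack(v)
#' dim(nuclear_channel(s))
#' @export
image_stack <- function(voxels, pixel_size_um = 0.553, z_step_um = 2.0,
                        channel_roles = c(probe1 = 1L, probe2 = 2L, nuclear = 3L)) {
  if (!is.array(voxels) || length(dim(voxels)) != 4L)
    .stopf("voxels must be a 4D (channel, z, y, x) array")
  if (dim(voxels)[2] < 1L) .stopf("stack needs at least one z-plane")
  if (any(voxels < 0)) .stopf("intensities must be >= 0 ADU")
  if (pixel_size_um <= 0 || z_step_um <= 0)
    .stopf("calibration must be positive")
  roles <- c("probe1", "probe2", "nuclear")
  if (!all(roles %in% names(channel_roles)))
    .stopf("channel_roles must name probe1, probe2 and nuclear")
  if (sum(names(channel_roles) == "nuclear") != 1L)
    .stopf("exactly one channel may have the nuclear role")
  if (any(channel_roles < 1L) || any(channel_roles > dim(voxels)[1]))
    .stopf("channel_roles out of range for %d channels", dim(voxels)[1])
  structure(list(voxels = voxels, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um,
                 channel_roles = channel_roles[roles]),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d channels, %d x %d x %d (z,y,x) voxels\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  calibration: %.3f um/px (xy), %.2f um z-step\n",
              x$pixel_size_um, x$z_step_um))
  cat(sprintf("  roles: probe1=ch%d probe2=ch%d nuclear=ch%d\n",
              x$channel_roles["probe1"], x$channel_roles["probe2"],
              x$channel_roles["nuclear"]))
  invisible(x)
}

#' Extract one channel of a stack as a 3D (z, y, x) volume
#'
#' @param stack an [image_stack].
#' @param channel integer channel index or role name
#'   (`"probe1"`, `"probe2"`, `"nuclear"`).
#' @return numeric array `(z, y, x)`.
#' @export
stack_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel)) {
    if (!channel %in% names(stack$channel_roles))
      .stopf("unknown channel role '%s'", channel)
    channel <- stack$channel_roles[[channel]]
  }
  v <- stack$voxels[channel, , , , drop = FALSE]
  dim(v) <- dim(stack$voxels)[-1]
  v
}

#' @rdname stack_channel
#' @export
nuclear_channel <- function(stack) stack_channel(stack, "nuclear")

# Internal scale: ADU are stored in TIFF pages as 16-bit unsigned samples
# (value / 65535 under the tiff package's [0,1] convention).
.TIFF_ADU_SCALE <- 65535

#' Read and write image stacks as multi-page TIFF
#'
#' Stacks are written as 16-bit multi-page TIFF, pages ordered
#' channel-major (all z of channel 1, then channel 2, ...). Intensities
#' are whole ADU (detector counts); non-integer voxel values are rounded
#' to the nearest ADU at write time and must not exceed 65535.
#' A JSON sidecar (`<path>.json`) records the axis order, shape,
#' calibration, channel roles and bit depth, so integer-valued volumes
#' round-trip exactly.
#'
#' @param stack an [image_stack].
#' @param path TIFF file path.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns an
#'   [image_stack].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  if (max(stack$voxels) > .TIFF_ADU_SCALE)
    .stopf("intensities exceed the 16-bit ADU range (max %.0f)",
           max(stack$voxels))
  pages <- vector("list", d[1] * d[2])
  i <- 0L
  for (ch in seq_len(d[1])) for (z in seq_len(d[2])) {
    i <- i + 1L
    m <- stack$voxels[ch, z, , ]
    dim(m) <- d[3:4]
    pages[[i]] <- m / .TIFF_ADU_SCALE
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- list(axes = "czyx", shape = as.integer(d),
                  pixel_size_um = stack$pixel_size_um,
                  z_step_um = stack$z_step_um,
                  channel_roles = as.list(stack$channel_roles),
                  adu_scale = .TIFF_ADU_SCALE)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) .stopf("missing sidecar: %s", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(side$shape)
  if (length(pages) != d[1] * d[2])
    .stopf("TIFF has %d pages, sidecar declares %d", length(pages), d[1] * d[2])
  v <- array(0, d)
  i <- 0L
  for (ch in seq_len(d[1])) for (z in seq_len(d[2])) {
    i <- i + 1L
    v[ch, z, , ] <- round(pages[[i]] * side$adu_scale)
  }
  image_stack(v, pixel_size_um = side$pixel_size_um,
              z_step_um = side$z_step_um,
              channel_roles = unlist(side$channel_roles))
}
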