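#' Integer label volume of nuclei-delineated ROIs
#'
#' Wraps a non-negative integer `(z, y, x)` array where 0 is background
#' and each positive value marks the voxels of one cell ROI. Labels may
#' come from the built-in segmenter ([segment_nuclei()]) or from an
#' external tool via [load_labels()].
#'
#' @param labels non-negative integer array `(z, y, x)`.
#' @param provenance `"builtin"` or `"external"`.
#' @param relabel if `TRUE`, map the sorted positive label values onto
#'   `1..K` (order-preserving); the mapping is attached as attribute
#'   `"relabel_map"` (data.frame `old`, `new`).
#' @return object of class `label_volume` with elements `labels`,
#'   `provenance`.
#' @export
label_volume <- function(labels, provenance = c("builtin", "external"),
                         relabel = FALSE) {
  provenance <- match.arg(provenance)
  if (!is.array(labels) || length(dim(labels)) != 3L)
    .stopf("labels must be a 3D (z, y, x) array")
  if (any(labels < 0) || any(labels != round(labels)))
    .stopf("labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  map <- NULL
  if (relabel) {
    ids <- sort(unique(labels[labels > 0L]))
    if (length(ids) && !identical(ids, seq_along(ids))) {
      map <- data.frame(old = ids, new = seq_along(ids))
      lut <- integer(max(ids) + 1L)
      lut[ids + 1L] <- seq_along(ids)
      labels[] <- lut[labels + 1L]
    }
  }
  out <- structure(list(labels = labels, provenance = provenance),
                   class = "label_volume")
  if (!is.null(map)) attr(out, "relabel_map") <- map
  out
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("label_volume (%s): %d x %d x %d voxels, %d labels\n",
              x$provenance, d[1], d[2], d[3], n_labels(x)))
  invisible(x)
}

#' Number of distinct positive labels in a label volume
#' @param labels a `label_volume`.
#' @return integer count.
#' @export
n_labels <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  length(unique(labels$labels[labels$labels > 0L]))
}

#' Write a label volume as an integer TIFF with JSON sidecar
#'
#' Volumes with fewer than 65536 labels are stored as 16-bit unsigned
#' pages (one page per z-plane); larger label counts fall back to 32-bit
#' float pages (exact for label values up to 2^24). The sidecar records
#' the shape and bit depth.
#'
#' @param labels a `label_volume`.
#' @param path TIFF path.
#' @param pixel_size_um,z_step_um optional calibration echoed in the sidecar.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, pixel_size_um = NA, z_step_um = NA) {
  stopifnot(inherits(labels, "label_volume"))
  L <- labels$labels
  mx <- max(L)
  bits <- if (mx < 65536L) 16L else 32L
  denom <- if (bits == 16L) 65535 else .TIFF_ADU_SCALE
  pages <- lapply(seq_len(dim(L)[1]), function(z) {
    m <- L[z, , ]; dim(m) <- dim(L)[2:3]
    m / denom
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  jsonlite::write_json(list(axes = "zyx", shape = as.integer(dim(L)),
                            bits = bits, denom = denom,
                            pixel_size_um = pixel_size_um,
                            z_step_um = z_step_um,
                            provenance = labels$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a nuclei label volume produced externally
#'
#' Reads an integer-valued TIFF (e.g. exported by a deep-learning
#' segmenter), checks that the pixel type is integral and optionally that
#' the shape matches a companion stack, and relabels non-contiguous ids
#' onto `1..K` preserving order (mapping in attribute `"relabel_map"`).
#'
#' @param path TIFF path (one page per z-plane). A `<path>.json` sidecar
#'   written by [write_labels()] is honoured when present.
#' @param companion_shape optional `(z, y, x)` shape the labels must match.
#' @return a `label_volume` with `provenance = "external"`.
#' @export
load_labels <- function(path, companion_shape = NULL) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path))
    jsonlite::read_json(side_path, simplifyVector = TRUE) else NULL
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  # 16-bit pages come back as raw integers under as.is; only the 32-bit
  # float fallback (sidecar bits == 32) needs rescaling by its denominator.
  denom <- if (!is.null(side) && isTRUE(side$bits == 32)) side$denom else 1
  vals <- lapply(pages, function(p) p * denom)
  flat <- unlist(vals)
  if (any(abs(flat - round(flat)) > 1e-6) || any(flat < 0))
    .stopf("label TIFF %s has non-integer pixel values; expected an integer label image", path)
  d <- c(length(vals), dim(vals[[1]]))
  L <- array(0L, d)
  for (z in seq_len(d[1])) L[z, , ] <- as.integer(round(vals[[z]]))
  if (!is.null(companion_shape) && !all(d == companion_shape))
    .stopf("label shape (%s) does not match companion stack shape (%s)",
           paste(d, collapse = "x"), paste(companion_shape, collapse = "x"))
  label_volume(L, provenance = "external", relabel = TRUE)
}

#' Remove labels outside a voxel-volume range
#'
#' Labels whose voxel count falls outside `[min_vox, max_vox]` are set to
#' background; surviving labels keep their identity (no renumbering).
#'
#' @param labels a `label_volume`.
#' @param min_vox,max_vox inclusive size bounds (voxels).
#' @return a `label_volume`.
#' @export
filter_labels_by_size <- function(labels, min_vox = 0, max_vox = Inf) {
  stopifnot(inherits(labels, "label_volume"))
  if (min_vox > max_vox) .stopf("min_vox must be <= max_vox")
  L <- labels$labels
  pos <- L[L > 0L]
  if (length(pos)) {
    sizes <- tabulate(pos)
    bad <- which(sizes > 0L & (sizes < min_vox | sizes > max_vox))
    if (length(bad)) L[L %in% bad] <- 0L
  }
  label_volume(L, provenance = labels$provenance)
}
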