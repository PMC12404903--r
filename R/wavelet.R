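#' \enc{À}{A} trous B3-spline wavelet decomposition of an image plane
#'
#' Isotropic undecimated ("with holes") wavelet transform used to enhance
#' diffraction-limited spots. Starting from \eqn{A_0 = } input, each
#' smoothing step convolves with the separable B3-spline kernel
#' \eqn{(1,4,6,4,1)/16} whose taps are spaced \eqn{2^{j-1}} pixels apart at
#' scale \eqn{j} (i.e. \eqn{2^{j-1}-1} zeros inserted between taps).
#' The detail plane at scale \eqn{j} is \eqn{W_j = A_{j-1} - A_j}, so the
#' transform reconstructs exactly: \eqn{\sum_j W_j + A_J =} input.
#' Boundaries are handled by mirror reflection, which keeps constant
#' backgrounds invariant (all detail coefficients are zero on a constant
#' plane, so a global offset never produces detections).
#'
#' @param plane 2D numeric matrix (one z-plane of one channel), finite.
#' @param J number of scales (>= 1). Small spots concentrate energy in
#'   scales 2-3 at typical confocal sampling.
#' @return Object of class `wavelet_planes`: list with `detail` (list of
#'   `J` matrices `W_1..W_J`), `smooth` (the final approximation `A_J`)
#'   and `J`.
#' @examples
#' p <- matrix(0, 33, 33); p[17, 17] <- 1
#' w <- atrous_decompose(p, J = 3)
#' w$detail[[1]][17, 17]  # 1 - (6/16)^2 = 0.859375
#' @export
atrous_decompose <- function(plane, J = 3L) {
  if (!is.matrix(plane) || !all(is.finite(plane)))
    .stopf("plane must be a finite numeric matrix")
  J <- as.integer(J)
  if (J < 1L) .stopf("J must be >= 1")
  extent <- 4L * 2L^(J - 1L) + 1L
  if (extent > 2L * min(dim(plane)))
    .stopf("scale %d kernel extent (%d px) exceeds twice the plane size", J, extent)
  taps <- c(1, 4, 6, 4, 1) / 16
  a <- plane
  detail <- vector("list", J)
  for (j in seq_len(J)) {
    step <- 2L^(j - 1L)
    offs <- step * (-2:2)
    s <- .conv_margin(a, taps, offs, 1L)
    s <- .conv_margin(s, taps, offs, 2L)
    detail[[j]] <- a - s
    a <- s
  }
  structure(list(detail = detail, smooth = a, J = J),
            class = "wavelet_planes")
}

#' Reconstruct a plane from its wavelet decomposition
#'
#' @param w a `wavelet_planes` object from [atrous_decompose()].
#' @return matrix equal to the original plane (to floating-point accuracy).
#' @export
atrous_reconstruct <- function(w) {
  stopifnot(inherits(w, "wavelet_planes"))
  Reduce(`+`, w$detail) + w$smooth
}
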