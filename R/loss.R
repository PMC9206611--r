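#' Normalised cross-correlation
#'
#' Global zero-mean, unit-variance correlation between two volumes, optionally
#' restricted to a foreground mask.  The training loss uses the whole volume:
#' the images entering the network are already masked (zero background), so
#' the plain global statistic is informative and keeps a nonzero gradient even
#' under poor initial overlap.  Returns 0 with a warning for zero-variance
#' input.
#'
#' @param a,b numeric arrays of identical shape (or \code{prost_volume}s).
#' @param mask optional logical/binary array restricting the correlation.
#' @return scalar in [-1, 1].
#' @export
ncc <- function(a, b, mask = NULL) {
  a <- if (inherits(a, "prost_volume")) a$data else a
  b <- if (inherits(b, "prost_volume")) b$data else b
  if (!identical(dim(a), dim(b))) stop("volumes must have identical shape")
  av <- as.vector(a); bv <- as.vector(b)
  if (!is.null(mask)) {
    m <- as.vector(mask) > 0
    av <- av[m]; bv <- bv[m]
  }
  A <- av - mean(av); B <- bv - mean(bv)
  sa <- sqrt(sum(A^2)); sb <- sqrt(sum(B^2))
  if (sa <= 1e-12 || sb <= 1e-12) {
    warning("zero-variance input to NCC; returning 0")
    return(0)
  }
  sum(A * B) / (sa * sb)
}

#' Deformation-field smoothness penalty
#'
#' Mean (over voxels) squared forward-difference spatial gradient of the
#' displacement, summed over the three channels and the three axes.
#'
#' @param phi 4D displacement array (nx, ny, nz, 3).
#' @return scalar >= 0 (0 for constant fields: translation is perfectly smooth).
#' @export
smoothness <- function(phi) {
  stopifnot(length(dim(phi)) == 4L, dim(phi)[4] == 3L)
  d <- dim(phi)[1:3]
  tot <- 0
  for (ch in 1:3) {
    u <- phi[, , , ch]
    tot <- tot + sum((u[2:d[1], , ] - u[1:(d[1] - 1), , ])^2) +
      sum((u[, 2:d[2], ] - u[, 1:(d[2] - 1), ])^2) +
      sum((u[, , 2:d[3]] - u[, , 1:(d[3] - 1)])^2)
  }
  tot / prod(d)
}

# binary dilation by r steps of the 6-neighbourhood
dilate_labels <- function(a, r = 2) {
  out <- a > 0
  for (step in seq_len(r)) {
    grown <- out
    for (ax in 1:3) for (by in c(-1, 1)) grown <- grown | (shift3(out * 1, ax, by) > 0)
    out <- grown
  }
  out
}

#' Registration training loss
#'
#' L = -NCC(V o T, V_f) - NCC(V o Psi, V_f) + delta * smoothness(phi):
#' image similarity of the affine-warped and fully-warped atlas against the
#' ground-truth volume, plus a weighted smoothness penalty on the local field.
#' Minimum -2, attained only under a perfect double match with zero-gradient
#' local field.
#'
#' @param output list with \code{warped_affine}, \code{warped_volume}
#'   (\code{prost_volume}s or arrays) and \code{phi} (4D mm field), as produced
#'   by \code{\link{register_case}}.
#' @param case a \code{registration_case} carrying the ground-truth target.
#' @param delta smoothness weight (default 0.01).
#' @return scalar loss.
#' @export
registration_loss <- function(output, case, delta = 0.01) {
  if (is.null(case$target)) stop("ground-truth target required for the loss")
  vf <- case$target$data
  wa <- if (inherits(output$warped_affine, "prost_volume"))
    output$warped_affine$data else output$warped_affine
  wv <- if (inherits(output$warped_volume, "prost_volume"))
    output$warped_volume$data else output$warped_volume
  -ncc(wa, vf) - ncc(wv, vf) + delta * smoothness(output$phi)
}
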