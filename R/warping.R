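#' 7-parameter affine pose
#'
#' The pose model used by the affine registration stage: three extrinsic Euler
#' rotations (degrees, applied as Rz(rz) Ry(ry) Rx(rx)), three translations
#' (mm) and one isotropic log-scale, acting about the volume centre (the
#' isocentre, i.e. the world origin).  The zero vector is the identity.
#'
#' @param rotation numeric(3) angles in degrees (about x, y, z).
#' @param translation numeric(3) in mm.
#' @param log_scale scalar; scale factor is \code{exp(log_scale)}.
#' @return object of class \code{affine_params}.
#' @export
affine_params <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                          log_scale = 0) {
  p <- c(rotation, translation, log_scale)
  if (length(p) != 7L || any(!is.finite(p))) stop("affine parameters must be 7 finite numbers")
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 log_scale = as.numeric(log_scale)),
            class = "affine_params")
}

#' @export
print.affine_params <- function(x, ...) {
  cat(sprintf("<affine_params> rot (deg) [%.3g, %.3g, %.3g], t (mm) [%.3g, %.3g, %.3g], scale %.4g\n",
              x$rotation[1], x$rotation[2], x$rotation[3],
              x$translation[1], x$translation[2], x$translation[3],
              exp(x$log_scale)))
  invisible(x)
}

as_affine_params <- function(p) {
  if (inherits(p, "affine_params")) return(p)
  p <- as.numeric(p)
  stopifnot(length(p) == 7L)
  affine_params(p[1:3], p[4:6], p[7])
}

#' @rdname affine_params
#' @param p an \code{affine_params} (or numeric(7) in the same order).
#' @return \code{affine_to_matrix}: the 4x4 homogeneous matrix
#'   \code{Translate(t) \%*\% R(angles) \%*\% exp(log_scale) I}.
#' @export
affine_to_matrix <- function(p) {
  p <- as_affine_params(p)
  R <- rot_z(p$rotation[3]) %*% rot_y(p$rotation[2]) %*% rot_x(p$rotation[1])
  M <- diag(4)
  M[1:3, 1:3] <- R * exp(p$log_scale)
  M[1:3, 4] <- p$translation
  M
}

#' Affine volume warp
#'
#' Backward warping: the output voxel at world position x takes the value
#' \code{vol(T^-1 x)} -- i.e. the volume content is moved by T.  Use
#' \code{mode = "nearest"} for label maps.
#'
#' @param vol a \code{prost_volume} (or 3D array, unit spacing).
#' @param tmat 4x4 homogeneous matrix (e.g. \code{\link{affine_to_matrix}}).
#' @param mode interpolation: \code{"linear"} or \code{"nearest"}.
#' @return a \code{prost_volume} on the same grid.
#' @export
warp_affine <- function(vol, tmat, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  vol <- as_volume(vol)
  if (abs(det(tmat)) < 1e-12) stop("singular affine transform")
  Minv <- solve(tmat)
  d <- dim(vol$data)
  W <- voxel_world_coords(d, vol$spacing)
  Wm <- W %*% t(Minv[1:3, 1:3])
  Wm[, 1] <- Wm[, 1] + Minv[1, 4]
  Wm[, 2] <- Wm[, 2] + Minv[2, 4]
  Wm[, 3] <- Wm[, 3] + Minv[3, 4]
  idx <- world_to_index(Wm, d, vol$spacing)
  vals <- sample_by_mode(vol$data, idx, mode)
  out <- prost_volume(array(vals, d), vol$spacing)
  if (!is.null(vol$labels)) {
    lv <- sample_by_mode(vol$labels, idx, "nearest")
    out$labels <- array(lv, d)
  }
  out
}

sample_by_mode <- function(arr, idx, mode) {
  if (mode == "linear") return(trilinear_kernel(arr, idx)$values)
  d <- dim(arr)
  i <- round(idx[, 1]); j <- round(idx[, 2]); k <- round(idx[, 3])
  ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  i[!ok] <- 1; j[!ok] <- 1; k[!ok] <- 1
  v <- arr[cbind(i, j, k)]
  v[!ok] <- 0
  v
}

# sample a (nx,ny,nz,3) displacement field (mm) at voxel index positions idx,
# edge-clamped so compositions do not pull in a spurious zero boundary.
sample_field <- function(field, idx) {
  trilinear_kernel(field, idx, mode = "edge")$values
}

base_index_grid <- function(d) {
  cbind(rep(seq_len(d[1]), times = d[2] * d[3]),
        rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
        rep(seq_len(d[3]), each = d[1] * d[2]))
}

mm_to_voxel <- function(u, spacing) {
  u[, 1] <- u[, 1] / spacing[1]; u[, 2] <- u[, 2] / spacing[2]
  u[, 3] <- u[, 3] / spacing[3]; u
}

#' Integrate a stationary velocity field by scaling and squaring
#'
#' The velocity field (mm, on the volume grid) is divided by 2^n and then
#' self-composed n times: u <- u + u o (Id + u), each composition by trilinear
#' resampling of the displacement field.  The result is a diffeomorphic
#' backward displacement field for smooth, bounded velocities.
#'
#' @param v 4D array (nx, ny, nz, 3) stationary velocity in mm.
#' @param n_steps number of squaring steps (default 7).
#' @param spacing grid spacing in mm (for the mm-to-voxel conversion when
#'   resampling).
#' @return 4D array, the integrated displacement field in mm.
#' @export
integrate_velocity <- function(v, n_steps = 7, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(v)) == 4L, dim(v)[4] == 3L, n_steps >= 0)
  d <- dim(v)[1:3]
  u <- v / 2^n_steps
  if (n_steps == 0) return(u)
  base <- base_index_grid(d)
  for (s in seq_len(n_steps)) {
    um <- matrix(u, prod(d), 3)
    idx <- base + mm_to_voxel(um, spacing)
    u <- array(um + sample_field(u, idx), dim(v))
  }
  u
}

#' Compose an affine transform with a local deformation field
#'
#' The network warps the atlas first by the affine transform T, then by the
#' local field phi (phi lives on the affine-warped grid).  The equivalent
#' single backward map is m(x) = T^-1 (x + phi(x)); this function returns it as
#' a displacement field Psi(x) = m(x) - x, so that one resampling
#' \code{warp_dense(vol, Psi)} reproduces the two-stage warp
#' \code{warp_dense(warp_affine(vol, T), phi)} up to interpolation error.
#'
#' @param tmat 4x4 affine matrix.
#' @param phi 4D displacement field (mm, backward convention).
#' @param spacing grid spacing in mm.
#' @return 4D displacement field Psi in mm.
#' @export
compose_affine_local <- function(tmat, phi, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(phi)) == 4L, dim(phi)[4] == 3L)
  if (abs(det(tmat)) < 1e-12) stop("singular affine transform")
  Minv <- solve(tmat)
  d <- dim(phi)[1:3]
  W <- index_to_world(base_index_grid(d), d, spacing)
  pm <- matrix(phi, prod(d), 3)
  Y <- W + pm
  Ym <- Y %*% t(Minv[1:3, 1:3])
  Ym[, 1] <- Ym[, 1] + Minv[1, 4]; Ym[, 2] <- Ym[, 2] + Minv[2, 4]
  Ym[, 3] <- Ym[, 3] + Minv[3, 4]
  array(Ym - W, dim(phi))
}

#' Warp a volume by a dense displacement field
#'
#' Backward warping: output(x) = vol(x + u(x)), with u in mm on the volume
#' grid; 0 outside the volume.  Use \code{mode = "nearest"} for label maps.
#'
#' @inheritParams warp_affine
#' @param field 4D array (nx, ny, nz, 3) displacement in mm.
#' @return a \code{prost_volume}.
#' @export
warp_dense <- function(vol, field, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  vol <- as_volume(vol)
  d <- dim(vol$data)
  if (!identical(dim(field)[1:3], d) || dim(field)[4] != 3L)
    stop("field grid does not match the volume")
  idx <- base_index_grid(d) + mm_to_voxel(matrix(field, prod(d), 3), vol$spacing)
  vals <- sample_by_mode(vol$data, idx, mode)
  out <- prost_volume(array(vals, d), vol$spacing)
  if (!is.null(vol$labels))
    out$labels <- array(sample_by_mode(vol$labels, idx, "nearest"), d)
  out
}

#' Jacobian determinant of a deformation
#'
#' Determinant of the spatial gradient of the map Id + u at every interior
#' voxel, by central finite differences in mm.  Values > 0 everywhere indicate
#' a locally invertible (orientation-preserving) deformation.
#'
#' @param field 4D displacement array (mm).
#' @param spacing grid spacing in mm.
#' @return 3D array of size dim - 2 (interior voxels only).
#' @export
jacobian_determinant <- function(field, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(field)) == 4L, dim(field)[4] == 3L)
  d <- dim(field)[1:3]
  if (any(d < 3L)) stop("grid too small for central differences")
  ii <- 2:(d[1] - 1); jj <- 2:(d[2] - 1); kk <- 2:(d[3] - 1)
  J <- vector("list", 9)
  n <- 1L
  for (ch in 1:3) {
    u <- field[, , , ch]
    dx <- (u[ii + 1, jj, kk] - u[ii - 1, jj, kk]) / (2 * spacing[1])
    dy <- (u[ii, jj + 1, kk] - u[ii, jj - 1, kk]) / (2 * spacing[2])
    dz <- (u[ii, jj, kk + 1] - u[ii, jj, kk - 1]) / (2 * spacing[3])
    J[[n]] <- dx + (ch == 1); J[[n + 1]] <- dy + (ch == 2); J[[n + 2]] <- dz + (ch == 3)
    n <- n + 3L
  }
  # det of rows (J1 J2 J3; J4 J5 J6; J7 J8 J9)
  J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
    J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
    J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
}

# Separable Gaussian smoothing of a 3D array (sigma in voxels per axis).
# Kernel rows are truncated at 4 sigma and renormalised (edge-corrected).
gauss_axis_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  i <- seq_len(n)
  K <- exp(-outer(i, i, "-")^2 / (2 * sigma^2))
  K[abs(outer(i, i, "-")) > ceiling(4 * sigma)] <- 0
  K / rowSums(K)
}

gaussian_smooth3d <- function(x, sigma) {
  sigma <- rep_len(sigma, 3L)
  d <- dim(x)
  x <- matrix(x, d[1], d[2] * d[3])
  x <- gauss_axis_matrix(d[1], sigma[1]) %*% x
  x <- array(x, d)
  x <- aperm(x, c(2, 1, 3))
  x <- matrix(x, d[2], d[1] * d[3])
  x <- gauss_axis_matrix(d[2], sigma[2]) %*% x
  x <- aperm(array(x, c(d[2], d[1], d[3])), c(2, 1, 3))
  x <- matrix(x, d[1] * d[2], d[3])
  x <- x %*% t(gauss_axis_matrix(d[3], sigma[3]))
  array(x, d)
}
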