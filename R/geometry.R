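#' Calibrated cone-beam projection geometry
#'
#' Parameterises one cone-beam acquisition.  The canonical (unrotated)
#' configuration places the X-ray source on the +y (anterior-posterior) axis at
#' \code{iso_mm} from the isocentre (the world origin), with the detector plane
#' perpendicular to the source-isocentre axis at \code{sdd_mm} from the source.
#' Detector axis u lies along world x and axis v along world z (cranio-caudal).
#' The LAO/RAO angle \eqn{\theta} rotates this configuration about the
#' cranio-caudal (z) axis -- positive \eqn{\theta} (LAO) is counter-clockwise
#' when viewed from the patient's head -- and the cranio-caudal angle rotates it
#' about the lateral (x) axis.
#'
#' @param lao_rao_deg LAO/RAO angle \eqn{\theta} in degrees; stored in
#'   \[-180, 180).
#' @param cranio_caudal_deg cranio-caudal angle in degrees (default 0).
#' @param sdd_mm source-detector distance in mm (default 1000).
#' @param iso_mm source-isocentre distance in mm (default 925); must be
#'   positive and smaller than \code{sdd_mm}.
#' @param detector_px integer(2) detector size (Sx, Sy) in pixels.
#' @param pixel_mm detector pixel spacing in mm/pixel (scalar or length 2).
#' @param k_samples number K of samples per ray (>= 2).
#' @param depth_window_mm length of the sampled depth window, centred on the
#'   isocentre, in mm.  Choose it at least the diagonal of the volume bounding
#'   box so the whole volume is covered at any rotation
#'   (see \code{\link{geometry_for_volume}}).
#' @return object of class \code{projection_geometry}.
#' @export
projection_geometry <- function(lao_rao_deg = 0, cranio_caudal_deg = 0,
                                sdd_mm = 1000, iso_mm = 925,
                                detector_px = c(64, 64), pixel_mm = 1,
                                k_samples = 64, depth_window_mm = 250) {
  num <- c(lao_rao_deg, cranio_caudal_deg, sdd_mm, iso_mm, depth_window_mm)
  if (any(!is.finite(num))) stop("invalid geometry: non-finite parameter")
  if (iso_mm <= 0 || iso_mm >= sdd_mm)
    stop("invalid geometry: need 0 < iso_mm < sdd_mm")
  detector_px <- as.integer(rep_len(detector_px, 2L))
  if (any(detector_px < 2L)) stop("invalid geometry: detector_px must be >= 2")
  if (k_samples < 2L) stop("invalid geometry: k_samples must be >= 2")
  pixel_mm <- rep_len(as.numeric(pixel_mm), 2L)
  if (any(pixel_mm <= 0)) stop("invalid geometry: pixel_mm must be positive")
  if (depth_window_mm <= 0) stop("invalid geometry: depth_window_mm must be positive")
  theta <- ((lao_rao_deg + 180) %% 360) - 180
  structure(list(lao_rao_deg = theta, cranio_caudal_deg = cranio_caudal_deg,
                 sdd_mm = sdd_mm, iso_mm = iso_mm, detector_px = detector_px,
                 pixel_mm = pixel_mm, k_samples = as.integer(k_samples),
                 depth_window_mm = depth_window_mm),
            class = "projection_geometry")
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat(sprintf(paste0("<projection_geometry> theta = %g deg, cc = %g deg, ",
                     "SDD = %g mm, iso = %g mm,\n  detector %d x %d px @ %g x %g mm, ",
                     "K = %d over %g mm depth window\n"),
              x$lao_rao_deg, x$cranio_caudal_deg, x$sdd_mm, x$iso_mm,
              x$detector_px[1], x$detector_px[2], x$pixel_mm[1], x$pixel_mm[2],
              x$k_samples, x$depth_window_mm))
  invisible(x)
}

#' Construct a geometry matched to a volume
#'
#' Convenience constructor: sets the depth window to the diagonal of the volume
#' bounding box, the number of ray samples (unless given) to the largest
#' volume dimension, and (unless given) a detector pixel spacing such that the
#' detector field of view covers the volume magnified at the isocentre
#' (magnification SDD/iso).
#'
#' @param vol a \code{prost_volume} (or 3D array).
#' @param ... arguments passed to \code{\link{projection_geometry}}.
#' @param pixel_mm optional override of the computed pixel spacing.
#' @export
geometry_for_volume <- function(vol, ..., pixel_mm = NULL) {
  vol <- as_volume(vol)
  ext <- dim(vol$data) * vol$spacing
  diag_mm <- sqrt(sum(ext^2))
  args <- list(...)
  if (is.null(args$detector_px)) args$detector_px <- c(64, 64)
  if (is.null(args$k_samples)) args$k_samples <- max(dim(vol$data))
  det <- as.integer(rep_len(args$detector_px, 2L))
  if (is.null(pixel_mm)) {
    sdd <- if (is.null(args$sdd_mm)) 1000 else args$sdd_mm
    iso <- if (is.null(args$iso_mm)) 925 else args$iso_mm
    mag <- sdd / iso
    # in-plane footprint never exceeds the bbox diagonal; small safety margin
    pixel_mm <- 1.05 * mag * diag_mm / min(det)
  }
  args$pixel_mm <- pixel_mm
  args$depth_window_mm <- diag_mm
  do.call(projection_geometry, args)
}

rot_z <- function(deg) {
  r <- deg * pi / 180; c_ <- cos(r); s_ <- sin(r)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

rot_x <- function(deg) {
  r <- deg * pi / 180; c_ <- cos(r); s_ <- sin(r)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}

rot_y <- function(deg) {
  r <- deg * pi / 180; c_ <- cos(r); s_ <- sin(r)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}

#' Geometry transform T_geom
#'
#' 4x4 homogeneous transform that rotates the canonical (theta = 0, cc = 0)
#' source/detector configuration into the actual acquisition geometry: rotation
#' by the LAO/RAO angle about the cranio-caudal (z) axis composed with rotation
#' by the cranio-caudal angle about the lateral (x) axis, about the isocentre.
#'
#' @param geom a \code{projection_geometry}.
#' @return 4x4 matrix (pure rotation; last row c(0,0,0,1)).
#' @export
build_geometry_transform <- function(geom) {
  stopifnot(inherits(geom, "projection_geometry"))
  R <- rot_z(geom$lao_rao_deg) %*% rot_x(geom$cranio_caudal_deg)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M
}

canonical_source <- function(geom) c(0, geom$iso_mm, 0)

#' X-ray source world position
#'
#' @inheritParams build_geometry_transform
#' @return numeric(3), mm; at distance \code{iso_mm} from the origin.
#' @export
source_position <- function(geom) {
  M <- build_geometry_transform(geom)
  as.vector(M[1:3, 1:3] %*% canonical_source(geom))
}

# detector frame in the canonical configuration
canonical_detector <- function(geom) {
  list(centre = c(0, geom$iso_mm - geom$sdd_mm, 0),
       e_u = c(1, 0, 0), e_v = c(0, 0, 1))
}

#' Canonical beam sampling grid G
#'
#' World coordinates of the K sampling points along the ray from the source to
#' each detector pixel centre, in the canonical (theta = 0, cc = 0) pose.  The
#' K samples are uniformly spaced in depth along each ray over a window of
#' length \code{depth_window_mm} centred on the isocentre distance.
#'
#' @inheritParams build_geometry_transform
#' @return list with \code{coords}, an (Sx, Sy, K, 3) array of mm coordinates,
#'   \code{spacing_mm} (depth increment along each ray) and the geometry.
#' @export
canonical_grid <- function(geom) {
  stopifnot(inherits(geom, "projection_geometry"))
  Sx <- geom$detector_px[1]; Sy <- geom$detector_px[2]; K <- geom$k_samples
  det <- canonical_detector(geom)
  s <- canonical_source(geom)
  u <- (seq_len(Sx) - (Sx + 1) / 2) * geom$pixel_mm[1]
  v <- (seq_len(Sy) - (Sy + 1) / 2) * geom$pixel_mm[2]
  # pixel centres (Sx*Sy x 3)
  P <- cbind(rep(u, times = Sy), 0, rep(v, each = Sx))
  P[, 1] <- det$centre[1] + P[, 1]
  P[, 2] <- det$centre[2]
  P[, 3] <- det$centre[3] + P[, 3]
  D <- P - matrix(s, nrow(P), 3, byrow = TRUE)
  D <- D / sqrt(rowSums(D^2))
  W <- geom$depth_window_mm
  t_k <- geom$iso_mm - W / 2 + (seq_len(K) - 1) * W / (K - 1)
  coords <- array(0, c(Sx, Sy, K, 3))
  for (k in seq_len(K)) {
    coords[, , k, 1] <- s[1] + t_k[k] * D[, 1]
    coords[, , k, 2] <- s[2] + t_k[k] * D[, 2]
    coords[, , k, 3] <- s[3] + t_k[k] * D[, 3]
  }
  list(coords = coords, spacing_mm = W / (K - 1), geom = geom)
}

#' Beam grid in the actual acquisition pose: T_geom applied to the canonical grid
#'
#' @inheritParams build_geometry_transform
#' @return as \code{\link{canonical_grid}}, rotated by the geometry transform.
#' @export
beam_grid <- function(geom) {
  g <- canonical_grid(geom)
  R <- build_geometry_transform(geom)[1:3, 1:3]
  d <- dim(g$coords)
  pts <- matrix(g$coords, prod(d[1:3]), 3) %*% t(R)
  g$coords <- array(pts, d)
  g
}

#' Inverse beam grid G^-1
#'
#' For each voxel centre of a volume grid, the fractional beam-space
#' coordinates (detector pixel i, j and depth sample k, 1-based) at which that
#' voxel samples the beam-space volume: the ray from the source through the
#' voxel is intersected with the detector plane, and the voxel's distance from
#' the source is mapped into the depth window.  Voxels whose ray misses the
#' detector, whose depth falls outside the window, or which coincide with the
#' source are masked invalid.
#'
#' @param volume_dim integer(3) voxel grid size.
#' @param volume_spacing numeric(3) spacing in mm.
#' @inheritParams build_geometry_transform
#' @return list with \code{coords} (nx, ny, nz, 3) fractional (i, j, k) and
#'   \code{mask} (nx, ny, nz) logical validity array.
#' @export
inverse_grid <- function(volume_dim, volume_spacing, geom) {
  stopifnot(inherits(geom, "projection_geometry"))
  if (any(volume_spacing <= 0)) stop("volume spacing must be positive")
  volume_dim <- as.integer(volume_dim)
  Sx <- geom$detector_px[1]; Sy <- geom$detector_px[2]; K <- geom$k_samples
  R <- build_geometry_transform(geom)[1:3, 1:3]
  s <- as.vector(R %*% canonical_source(geom))
  det <- canonical_detector(geom)
  dc <- as.vector(R %*% det$centre)
  eu <- as.vector(R %*% det$e_u)
  ev <- as.vector(R %*% det$e_v)
  a <- -s / sqrt(sum(s^2))              # unit source -> isocentre axis

  X <- voxel_world_coords(volume_dim, volume_spacing)
  Dx <- X[, 1] - s[1]; Dy <- X[, 2] - s[2]; Dz <- X[, 3] - s[3]
  t_vox <- sqrt(Dx^2 + Dy^2 + Dz^2)
  denom <- (Dx * a[1] + Dy * a[2] + Dz * a[3])
  ok <- t_vox > 1e-9 & denom > 1e-9
  scale <- ifelse(ok, geom$sdd_mm / denom, 0)   # t_hit / t_vox... see below
  # detector intersection q = s + (sdd/ (d.a)) * d   with d unnormalised
  qx <- s[1] + scale * Dx; qy <- s[2] + scale * Dy; qz <- s[3] + scale * Dz
  du <- (qx - dc[1]) * eu[1] + (qy - dc[2]) * eu[2] + (qz - dc[3]) * eu[3]
  dv <- (qx - dc[1]) * ev[1] + (qy - dc[2]) * ev[2] + (qz - dc[3]) * ev[3]
  i <- du / geom$pixel_mm[1] + (Sx + 1) / 2
  j <- dv / geom$pixel_mm[2] + (Sy + 1) / 2
  W <- geom$depth_window_mm
  k <- (t_vox - (geom$iso_mm - W / 2)) / (W / (K - 1)) + 1
  valid <- ok & i >= 1 & i <= Sx & j >= 1 & j <= Sy & k >= 1 & k <= K
  i[!valid] <- 0; j[!valid] <- 0; k[!valid] <- 0
  list(coords = array(c(i, j, k), c(volume_dim, 3L)),
       mask = array(valid, volume_dim), geom = geom,
       spacing = rep_len(as.numeric(volume_spacing), 3L))
}

#' Read / write projection geometries as YAML or JSON
#'
#' Keys: \code{lao_rao_deg}, \code{cranio_caudal_deg}, \code{sdd_mm},
#' \code{iso_mm}, \code{detector_px}, \code{pixel_mm}, \code{k_samples},
#' \code{depth_window_mm}.  Format chosen by file extension (.yaml/.yml/.json).
#'
#' @param geom a \code{projection_geometry}.
#' @param path output file path.
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "projection_geometry"))
  rec <- unclass(geom)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(rec, path)
  }
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  rec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  projection_geometry(lao_rao_deg = rec$lao_rao_deg,
                      cranio_caudal_deg = rec$cranio_caudal_deg,
                      sdd_mm = rec$sdd_mm, iso_mm = rec$iso_mm,
                      detector_px = unlist(rec$detector_px),
                      pixel_mm = unlist(rec$pixel_mm),
                      k_samples = rec$k_samples,
                      depth_window_mm = rec$depth_window_mm)
}
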