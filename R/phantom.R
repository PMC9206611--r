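#' Specification of a femur-like analytic phantom
#'
#' The phantom is a solid built from three analytic primitives in the canonical
#' femur frame (shaft axis along the cranio-caudal z axis, neck pointing
#' laterally in the x-z plane): a cylindrical shaft, a spherical head and a
#' tapered neck capsule joining them.  A cortical shell of higher intensity
#' surrounds a trabecular interior; the binary label map is the solid support.
#' Intensities at the solid boundary are anti-aliased over half a voxel so the
#' phantom has a well-defined continuous intensity function (useful as an
#' analytic oracle for warps and projections).
#'
#' Geometric defaults are scaled from the volume extent so the phantom (with
#' the default +/-10 % shape jitter and pose range) stays inside the grid at
#' any volume size.
#'
#' @param shape integer(3) voxel grid size (default 96 x 64 x 96).
#' @param spacing numeric(3) mm (default 0.664 x 0.664 x 1).
#' @param shaft_radius,head_radius mm; defaults scaled from the extent.
#' @param neck_angle degrees between shaft axis and neck axis (default 130,
#'   the typical femoral neck-shaft angle).
#' @param cortical_thickness mm (default 0.25 * shaft radius).
#' @param intensities numeric(3): background, trabecular, cortical (must be
#'   increasing).
#' @param noise_sigma standard deviation of optional additive Gaussian
#'   intensity noise (default 0).
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(96, 64, 96), spacing = c(0.664, 0.664, 1),
                         shaft_radius = NULL, head_radius = NULL,
                         neck_angle = 130, cortical_thickness = NULL,
                         intensities = c(0, 0.4, 1), noise_sigma = 0) {
  shape <- as.integer(rep_len(shape, 3L)); spacing <- rep_len(as.numeric(spacing), 3L)
  ext <- shape * spacing
  if (is.null(shaft_radius)) shaft_radius <- 0.105 * min(ext)
  if (is.null(head_radius)) head_radius <- 1.4 * shaft_radius
  if (is.null(cortical_thickness)) cortical_thickness <- 0.25 * shaft_radius
  if (shaft_radius <= 0 || head_radius <= 0 || cortical_thickness <= 0)
    stop("radii and cortical thickness must be positive")
  if (!(intensities[1] < intensities[2] && intensities[2] < intensities[3]))
    stop("intensities must be ordered background < trabecular < cortical")
  structure(list(shape = shape, spacing = spacing, shaft_radius = shaft_radius,
                 head_radius = head_radius, neck_angle = neck_angle,
                 cortical_thickness = cortical_thickness,
                 intensities = intensities, noise_sigma = noise_sigma),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> %d x %d x %d @ (%g, %g, %g) mm; shaft r %.2f mm, ",
                     "head r %.2f mm, neck %g deg, shell %.2f mm\n"),
              x$shape[1], x$shape[2], x$shape[3], x$spacing[1], x$spacing[2],
              x$spacing[3], x$shaft_radius, x$head_radius, x$neck_angle,
              x$cortical_thickness))
  invisible(x)
}

# run expr under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# concrete primitive placement for one phantom instance (optionally jittered)
draw_phantom_params <- function(spec, jitter = FALSE) {
  ext <- spec$shape * spec$spacing
  r_s <- spec$shaft_radius
  r_h <- spec$head_radius
  ang <- spec$neck_angle
  if (jitter) {
    r_s <- r_s * runif(1, 0.9, 1.1)
    r_h <- r_h * runif(1, 0.9, 1.1)
    ang <- ang + runif(1, -5, 5)
  }
  alpha <- (180 - ang) * pi / 180          # neck axis angle from +z
  x_s <- -0.13 * ext[1]
  z_bot <- -0.42 * ext[3]
  z_top <- 0.05 * ext[3]
  x_h <- 0.15 * ext[1]
  P0 <- c(x_s, 0, z_top)
  C <- c(x_h, 0, z_top + (x_h - x_s) / tan(alpha))
  reach <- c(abs(C[1]) + r_h, r_h, C[3] + r_h)
  if (any(reach > 0.5 * ext) || abs(x_s) + r_s > 0.5 * ext[1] ||
      r_s > 0.5 * ext[2] || abs(z_bot) > 0.49 * ext[3])
    stop("phantom geometry exceeds the volume extent")
  list(r_s = r_s, r_h = r_h, C = C, P0 = P0, z_bot = z_bot, z_top = z_top,
       r_n0 = 0.85 * r_s, r_n1 = 0.7 * r_h)
}

# signed inside-distance (mm, > 0 inside) of the union solid at points P (n x 3)
phantom_sdf <- function(P, pp) {
  # head sphere
  d_head <- pp$r_h - sqrt((P[, 1] - pp$C[1])^2 + (P[, 2] - pp$C[2])^2 +
                            (P[, 3] - pp$C[3])^2)
  # shaft cylinder (top extended into the joint region)
  rho <- sqrt((P[, 1] - pp$P0[1])^2 + P[, 2]^2)
  d_shaft <- pmin(pp$r_s - rho, P[, 3] - pp$z_bot,
                  pp$z_top + 0.5 * pp$r_s - P[, 3])
  # neck: tapered capsule from P0 to C
  axis <- pp$C - pp$P0
  L <- sqrt(sum(axis^2)); dir <- axis / L
  t <- ((P[, 1] - pp$P0[1]) * dir[1] + (P[, 2] - pp$P0[2]) * dir[2] +
          (P[, 3] - pp$P0[3]) * dir[3])
  t <- pmin(pmax(t, 0), L)
  qx <- pp$P0[1] + t * dir[1]; qy <- pp$P0[2] + t * dir[2]; qz <- pp$P0[3] + t * dir[3]
  radial <- sqrt((P[, 1] - qx)^2 + (P[, 2] - qy)^2 + (P[, 3] - qz)^2)
  d_neck <- (pp$r_n0 + (t / L) * (pp$r_n1 - pp$r_n0)) - radial
  pmax(d_head, d_shaft, d_neck)
}

#' Continuous phantom intensity function
#'
#' Returns a function that evaluates the phantom's anti-aliased intensity at
#' arbitrary world points (mm), enabling analytic references for interpolation
#' and warping error measurements.
#'
#' @param spec a \code{phantom_spec}.
#' @param params primitive placement as attached to a generated phantom
#'   (\code{attr(vol, "params")}); defaults to the canonical (unjittered) one.
#' @return function(P) taking an (n x 3) matrix of world mm points.
#' @export
phantom_intensity <- function(spec, params = NULL) {
  if (is.null(params)) params <- draw_phantom_params(spec, jitter = FALSE)
  aa <- 0.5 * min(spec$spacing)
  lv <- spec$intensities
  tc <- spec$cortical_thickness
  function(P) {
    d <- phantom_sdf(P, params)
    w_in <- pmin(pmax(d / aa, 0), 1)
    w_trab <- pmin(pmax((d - tc) / aa, 0), 1)
    lv[1] + w_in * ((lv[3] - lv[1]) + (lv[2] - lv[3]) * w_trab)
  }
}

#' Generate a phantom volume with label map
#'
#' Rasterises the analytic phantom at the voxel centres.  \code{seed = 0}
#' produces the canonical (atlas) instance; any other seed applies per-instance
#' shape jitter (radii +/-10 %, neck angle +/-5 deg), emulating inter-subject
#' variation.  Labels are the solid support at voxel centres.
#'
#' @param spec a \code{phantom_spec}.
#' @param seed integer; 0 (default) = canonical instance, otherwise jittered.
#' @return a \code{prost_volume} with \code{labels} and attribute
#'   \code{"params"} (the primitive placement used).
#' @export
make_phantom <- function(spec, seed = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(seed, {
    pp <- draw_phantom_params(spec, jitter = seed != 0)
    P <- voxel_world_coords(spec$shape, spec$spacing)
    f <- phantom_intensity(spec, pp)
    vals <- f(P)
    lab <- as.numeric(phantom_sdf(P, pp) > 0)
    if (spec$noise_sigma > 0)
      vals <- vals + rnorm(length(vals), 0, spec$noise_sigma)
    v <- prost_volume(array(vals, spec$shape), spec$spacing,
                      labels = array(lab, spec$shape))
    attr(v, "params") <- pp
    v
  })
}

#' Random affine pose
#'
#' Uniform pose perturbation in the canonical femur frame: rotations within
#' +/-\code{rot_deg} per anatomical axis (default 10 deg, matching
#' extension/flexion, ab-/adduction and internal/external rotation ranges),
#' translations within +/-\code{trans_mm}, isotropic log-scale within
#' +/-log(1 + \code{scale_frac}).
#'
#' @param seed integer seed (draws are reproducible per seed).
#' @param rot_deg,trans_mm,scale_frac range half-widths (set 0 to disable).
#' @return an \code{\link{affine_params}}.
#' @export
random_pose <- function(seed, rot_deg = 10, trans_mm = 4, scale_frac = 0.05) {
  stopifnot(rot_deg >= 0, trans_mm >= 0, scale_frac >= 0)
  with_seed(seed, {
    affine_params(rotation = runif(3, -rot_deg, rot_deg),
                  translation = runif(3, -trans_mm, trans_mm),
                  log_scale = runif(1, log(1 - scale_frac), log(1 + scale_frac)))
  })
}

#' Random smooth stationary velocity field
#'
#' Three channels of white noise are Gaussian-smoothed (sigma in voxels) and
#' rescaled so the maximum vector norm equals \code{amplitude} (mm).  Integrate
#' with \code{\link{integrate_velocity}} to obtain a diffeomorphic local
#' deformation.
#'
#' @param seed integer seed.
#' @param amplitude maximum velocity norm in mm (default 4).
#' @param smoothness_sigma Gaussian sigma in voxels (default 3).
#' @param grid_shape integer(3) field grid.
#' @return 4D array (grid_shape, 3) in mm.
#' @export
random_deformation <- function(seed, amplitude = 4, smoothness_sigma = 3,
                               grid_shape = c(96, 64, 96)) {
  stopifnot(amplitude >= 0)
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  with_seed(seed, {
    v <- array(rnorm(prod(grid_shape) * 3), c(grid_shape, 3L))
    if (amplitude == 0) return(v * 0)
    for (ch in 1:3) v[, , , ch] <- gaussian_smooth3d(v[, , , ch], smoothness_sigma)
    nrm <- sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2)
    v * (amplitude / max(nrm))
  })
}

#' Geometries for a biplanar acquisition of a phantom
#'
#' Builds the AP and LAT projection geometries for a phantom volume.  In
#' \code{"orthogonal"} mode the LAO/RAO angles are exactly 0 and 90 degrees; in
#' \code{"generalised"} mode each is offset by a uniform draw within
#' +/-\code{theta_range_deg} (generalised projection geometries).
#'
#' @param spec a \code{phantom_spec}.
#' @param mode \code{"orthogonal"} or \code{"generalised"}.
#' @param seed seed for the generalised-mode angle draws.
#' @param detector_px integer(2) detector size in pixels.
#' @param k_samples samples per ray.
#' @param theta_range_deg half-range of the oblique angle draws (default 30).
#' @return list with \code{ap} and \code{lat} \code{projection_geometry}.
#' @export
case_geometries <- function(spec, mode = c("orthogonal", "generalised"),
                            seed = 0, detector_px = c(48, 64), k_samples = 32,
                            theta_range_deg = 30) {
  mode <- match.arg(mode)
  vol_stub <- list(data = array(0, spec$shape), spacing = spec$spacing)
  class(vol_stub) <- "prost_volume"
  th <- c(0, 90)
  if (mode == "generalised")
    th <- th + with_seed(seed, runif(2, -theta_range_deg, theta_range_deg))
  list(ap = geometry_for_volume(vol_stub, lao_rao_deg = th[1],
                                detector_px = detector_px, k_samples = k_samples),
       lat = geometry_for_volume(vol_stub, lao_rao_deg = th[2],
                                 detector_px = detector_px, k_samples = k_samples))
}

#' Generate a complete synthetic registration case
#'
#' Builds one atlas/target pair with biplanar DRRs: the atlas is the canonical
#' phantom; the target is a shape-jittered phantom instance warped by a random
#' affine pose composed with a random local diffeomorphic deformation (the
#' stored ground truth).  DRRs of the target are rendered in both geometries,
#' masked by the projected target labels, downsampled to the network input
#' size and min-max normalised.
#'
#' @param spec a \code{phantom_spec}.
#' @param seed integer; drives shape jitter, pose, deformation and (in
#'   generalised mode) the projection angles.
#' @param input_px integer(2) network input size; DRRs are rendered at
#'   2 x \code{input_px} detector resolution and downsampled.
#' @param k_samples samples per ray for the DRRs.
#' @param mode projection mode, see \code{\link{case_geometries}}.
#' @param rot_deg,trans_mm,scale_frac pose ranges (see \code{\link{random_pose}}).
#' @param deform_amplitude_mm,deform_sigma_vox local deformation parameters
#'   (see \code{\link{random_deformation}}); amplitude 0 disables.
#' @param jitter_shape apply per-instance shape jitter to the target?
#' @return object of class \code{registration_case}: atlas, target, DRR pair,
#'   geometries, masks and ground truth (pose, velocity, phi, psi).
#' @export
make_case <- function(spec, seed, input_px = c(24, 32), k_samples = 32,
                      mode = c("orthogonal", "generalised"),
                      rot_deg = 10, trans_mm = 4, scale_frac = 0.05,
                      deform_amplitude_mm = 4, deform_sigma_vox = 3,
                      jitter_shape = TRUE) {
  mode <- match.arg(mode)
  atlas <- make_phantom(spec, 0)
  instance <- if (jitter_shape) make_phantom(spec, seed) else atlas
  pose <- random_pose(seed * 3L + 1L, rot_deg, trans_mm, scale_frac)
  tmat <- affine_to_matrix(pose)
  vel <- random_deformation(seed * 3L + 2L, deform_amplitude_mm,
                            deform_sigma_vox, spec$shape)
  phi <- integrate_velocity(vel, n_steps = 7, spacing = spec$spacing)
  psi <- compose_affine_local(tmat, phi, spacing = spec$spacing)
  target <- warp_dense(instance, psi)
  geoms <- case_geometries(spec, mode, seed = seed * 3L, k_samples = k_samples,
                           detector_px = 2L * as.integer(input_px))
  render <- function(geom) {
    p <- drr(target, geom)
    mask <- project_labels(prost_volume(target$labels, spec$spacing), geom)
    img <- downsample_image(p$pixels * mask, input_px)
    list(image = normalise01(img),
         mask = (downsample_image(mask, input_px) > 0.5) * 1)
  }
  ap <- render(geoms$ap); lat <- render(geoms$lat)
  structure(list(atlas = atlas, target = target, seed = seed,
                 drr_ap = ap$image, drr_lat = lat$image,
                 mask_ap = ap$mask, mask_lat = lat$mask,
                 geom_ap = geoms$ap, geom_lat = geoms$lat,
                 input_px = as.integer(input_px), spec = spec,
                 truth = list(pose = pose, velocity = vel, phi = phi, psi = psi)),
            class = "registration_case")
}

#' @export
print.registration_case <- function(x, ...) {
  cat(sprintf("<registration_case> seed %d, volume %s, DRRs %d x %d (theta %g / %g deg)\n",
              x$seed, paste(dim(x$atlas$data), collapse = "x"),
              x$input_px[1], x$input_px[2],
              x$geom_ap$lao_rao_deg, x$geom_lat$lao_rao_deg))
  invisible(x)
}

#' Generate and write a dataset of synthetic cases
#'
#' Writes \code{n_cases} case directories (NIfTI volumes and DRRs, YAML
#' geometries, JSON ground truth) plus a train/validation/test manifest with a
#' 60/20/20 split (by case order) and the global seed.
#'
#' @param n_cases number of cases (>= 1).
#' @param seed global seed; case i uses a seed derived from it.
#' @param out_dir output directory (created if missing).
#' @param spec a \code{phantom_spec}.
#' @param split fractions for train/val/test (default c(0.6, 0.2, 0.2)).
#' @param ... passed to \code{\link{make_case}} (mode, pose ranges, ...).
#' @return the manifest, invisibly (also written as manifest.yaml).
#' @export
make_dataset <- function(n_cases, seed, out_dir, spec = phantom_spec(),
                         split = c(0.6, 0.2, 0.2), ...) {
  stopifnot(n_cases >= 1)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory")
  ids <- sprintf("case_%04d", seq_len(n_cases))
  n_train <- floor(split[1] * n_cases); n_val <- floor(split[2] * n_cases)
  roles <- c(rep("train", n_train), rep("val", n_val),
             rep("test", n_cases - n_train - n_val))
  for (i in seq_len(n_cases)) {
    cs <- case_seed(seed, i)
    case <- make_case(spec, cs, ...)
    cdir <- file.path(out_dir, ids[i])
    dir.create(cdir, showWarnings = FALSE)
    write_volume(case$atlas, file.path(cdir, "atlas.nii.gz"))
    write_volume(prost_volume(case$atlas$labels, spec$spacing),
                 file.path(cdir, "atlas_labels.nii.gz"))
    write_volume(case$target, file.path(cdir, "target.nii.gz"))
    write_volume(prost_volume(case$target$labels, spec$spacing),
                 file.path(cdir, "target_labels.nii.gz"))
    write_projection(case$drr_ap, file.path(cdir, "drr_ap.nii.gz"))
    write_projection(case$drr_lat, file.path(cdir, "drr_lat.nii.gz"))
    write_geometry(case$geom_ap, file.path(cdir, "geom_ap.yaml"))
    write_geometry(case$geom_lat, file.path(cdir, "geom_lat.yaml"))
    tr <- case$truth
    jsonlite::write_json(list(seed = cs,
                              pose = list(rotation = tr$pose$rotation,
                                          translation = tr$pose$translation,
                                          log_scale = tr$pose$log_scale)),
                         file.path(cdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    write_field(tr$psi, spec$spacing, file.path(cdir, "psi_true.nii.gz"))
  }
  manifest <- list(seed = seed, n_cases = n_cases,
                   split = split(ids, factor(roles, c("train", "val", "test"))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

case_seed <- function(seed, i) (seed + i * 7919L) %% 2147483647L
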