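#' Projective spatial transform (ProST): volume to beam space
#'
#' Resamples a 3D volume trilinearly at the beam sampling grid (the canonical
#' grid rotated by the geometry transform), producing the ray-aligned
#' "beam-space" volume: \code{V_beam(i,j,k)} is the volume interpolated at the
#' k-th sample of the ray from the source to detector pixel (i,j).  Sampling
#' points outside the volume contribute 0.  The operator is linear in the voxel
#' values.
#'
#' @param vol a \code{prost_volume} (or 3D array with unit spacing).
#' @param geom a \code{projection_geometry}.
#' @return object of class \code{beam_volume}: list with \code{values}
#'   (Sx, Sy, K array), \code{spacing_mm} (depth increment) and \code{geom}.
#' @export
prost <- function(vol, geom) {
  vol <- as_volume(vol)
  g <- beam_grid(geom)
  d <- dim(g$coords)
  idx <- world_to_index(matrix(g$coords, prod(d[1:3]), 3),
                        dim(vol$data), vol$spacing)
  vals <- trilinear_kernel(vol$data, idx)$values
  structure(list(values = array(vals, d[1:3]), spacing_mm = g$spacing_mm,
                 geom = geom), class = "beam_volume")
}

#' @export
print.beam_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<beam_volume> %d x %d detector px, K = %d, depth step %.3g mm\n",
              d[1], d[2], d[3], x$spacing_mm))
  invisible(x)
}

#' Parallel projection of a beam-space volume
#'
#' Sums the beam-space volume along the ray (depth) axis.  With
#' \code{scaled = TRUE} (default) the sum is multiplied by the depth increment
#' in mm, approximating the line integral along each cone-beam ray.
#'
#' @param beam a \code{beam_volume} from \code{\link{prost}}.
#' @param scaled multiply by the sample spacing (line-integral scaling)?
#' @return object of class \code{projection2d}: list with \code{pixels}
#'   (Sx x Sy matrix) and \code{geom}.
#' @export
project <- function(beam, scaled = TRUE) {
  stopifnot(inherits(beam, "beam_volume"))
  d <- dim(beam$values)
  px <- rowSums(matrix(beam$values, d[1] * d[2], d[3]))
  if (scaled) px <- px * beam$spacing_mm
  structure(list(pixels = matrix(px, d[1], d[2]), geom = beam$geom),
            class = "projection2d")
}

#' @export
print.projection2d <- function(x, ...) {
  cat(sprintf("<projection2d> %d x %d px, range [%.3g, %.3g]\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Digitally reconstructed radiograph
#'
#' Cone-beam projection of a volume: \code{project(prost(vol, geom))}.
#' Intensities are monoenergetic line integrals of the volume; no spectral or
#' scatter physics.
#'
#' @inheritParams prost
#' @inheritParams project
#' @return a \code{projection2d}.
#' @export
drr <- function(vol, geom, scaled = TRUE) project(prost(vol, geom), scaled)

#' Inverse projective spatial transform (inv-ProST): beam space to volume
#'
#' Samples a beam-space volume trilinearly at each physical voxel's fractional
#' beam coordinates (the inverse grid).  Voxels outside the cone beam are set
#' to exactly 0.  Applying \code{inv_prost} after \code{\link{prost}}
#' reproduces the volume up to interpolation error inside the cone.
#'
#' @param beam a \code{beam_volume}.
#' @param inv_grid an inverse grid from \code{\link{inverse_grid}}; its
#'   geometry must match the beam volume's.
#' @return a \code{prost_volume} on the inverse grid's voxel grid.
#' @export
inv_prost <- function(beam, inv_grid) {
  stopifnot(inherits(beam, "beam_volume"))
  gb <- beam$geom; gi <- inv_grid$geom
  if (!identical(gb$detector_px, gi$detector_px) ||
      gb$k_samples != gi$k_samples ||
      abs(gb$lao_rao_deg - gi$lao_rao_deg) > 1e-9 ||
      abs(gb$cranio_caudal_deg - gi$cranio_caudal_deg) > 1e-9)
    stop("beam volume and inverse grid geometries do not match")
  vd <- dim(inv_grid$mask)
  idx <- matrix(inv_grid$coords, prod(vd), 3)
  vals <- trilinear_kernel(beam$values, idx)$values
  vals[!as.vector(inv_grid$mask)] <- 0
  spacing <- if (is.null(inv_grid$spacing)) c(1, 1, 1) else inv_grid$spacing
  prost_volume(array(vals, vd), spacing = spacing)
}

#' Project a binary label map to a 2D mask
#'
#' The label volume is projected like a DRR and binarised: a detector pixel is
#' inside the mask when its ray intersects the labelled region by more than
#' \code{threshold} times the sample spacing (default: any positive
#' intersection).  Used to mask radiographs before they enter the network.
#'
#' @param labels binary 3D array or a \code{prost_volume} whose \code{data} is
#'   the binary label map.
#' @param geom a \code{projection_geometry}.
#' @param threshold fraction of one sample spacing required to switch a pixel
#'   on (default 0: any intersection).
#' @param spacing voxel spacing when \code{labels} is a bare array.
#' @return binary matrix (Sx x Sy).
#' @export
project_labels <- function(labels, geom, threshold = 0, spacing = c(1, 1, 1)) {
  vol <- as_volume(labels, spacing)
  if (!all(vol$data %in% c(0, 1))) stop("labels must be binary")
  p <- drr(vol, geom, scaled = TRUE)
  (p$pixels > threshold * beam_grid(geom)$spacing_mm) * 1
}

#' Min-max normalise an image to [0, 1]
#'
#' @param img numeric matrix or array.
#' @return same shape, linearly rescaled so min = 0 and max = 1; a constant
#'   image maps to all zeros.
#' @export
normalise01 <- function(img) {
  rng <- range(img)
  if (rng[2] - rng[1] <= 0) return(img * 0)
  (img - rng[1]) / (rng[2] - rng[1])
}

#' Downsample a 2D image to a target size
#'
#' Area averaging by the largest integer factor per axis, followed by bilinear
#' interpolation to the exact target size (the pipeline used to bring
#' detector-resolution radiographs down to the network input size).
#'
#' @param img numeric matrix.
#' @param target_px integer(2) output size.
#' @return matrix of size \code{target_px}.
#' @export
downsample_image <- function(img, target_px) {
  target_px <- as.integer(rep_len(target_px, 2L))
  d <- dim(img)
  f <- pmax(1L, d %/% target_px)
  if (any(f > 1L)) {
    nx <- (d[1] %/% f[1]) * f[1]; ny <- (d[2] %/% f[2]) * f[2]
    img <- img[seq_len(nx), seq_len(ny), drop = FALSE]
    img <- array(img, c(f[1], nx %/% f[1], f[2], ny %/% f[2]))
    img <- apply(img, c(2, 4), mean)
  }
  d <- dim(img)
  if (identical(d, target_px)) return(img)
  # bilinear resize on pixel-centre alignment
  sx <- d[1] / target_px[1]; sy <- d[2] / target_px[2]
  xi <- (seq_len(target_px[1]) - 0.5) * sx + 0.5
  yi <- (seq_len(target_px[2]) - 0.5) * sy + 0.5
  xi <- pmin(pmax(xi, 1), d[1]); yi <- pmin(pmax(yi, 1), d[2])
  x0 <- pmin(floor(xi), d[1] - 1); y0 <- pmin(floor(yi), d[2] - 1)
  fx <- xi - x0; fy <- yi - y0
  img[x0, y0] * outer(1 - fx, 1 - fy) + img[x0 + 1, y0] * outer(fx, 1 - fy) +
    img[x0, y0 + 1] * outer(1 - fx, fy) + img[x0 + 1, y0 + 1] * outer(fx, fy)
}

#' Write / read a 2D projection as NIfTI or PNG
#'
#' NIfTI preserves floating-point intensities and is the lossless route; PNG
#' (requires the \pkg{png} package) writes the image min-max rescaled and
#' 8-bit quantised, for quick inspection.  16-bit PNGs are supported on read.
#'
#' @param proj a \code{projection2d} or plain matrix.
#' @param path output path (.nii/.nii.gz or .png).
#' @export
write_projection <- function(proj, path) {
  px <- if (inherits(proj, "projection2d")) proj$pixels else proj
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("PNG output requires the 'png' package")
    png::writePNG(t(normalise01(px)), path, dpi = NULL)
  } else {
    RNifti::writeNifti(RNifti::asNifti(array(px, c(dim(px), 1))), path)
  }
  invisible(path)
}

#' @rdname write_projection
#' @export
read_projection <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("PNG input requires the 'png' package")
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1]
    t(a)
  } else {
    a <- as.array(RNifti::readNifti(path))
    if (length(dim(a)) == 3L) a <- a[, , 1, drop = TRUE]
    a
  }
}
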