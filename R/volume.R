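#' 3D image volume
#'
#' Container for a 3D intensity volume on a regular grid, optionally carrying a
#' binary label map on the same grid.  The world coordinate frame is in mm,
#' right-handed, with the origin (the imaging isocentre) at the centre of the
#' volume: array axis 1 is the patient's lateral (x) axis, axis 2 the
#' anterior-posterior (y) axis and axis 3 the cranio-caudal (z) axis.  Voxel
#' \code{(i,j,k)} (1-based) has world position
#' \code{(c(i,j,k) - (dim+1)/2) * spacing}.
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param spacing numeric(3), voxel spacing in mm (all > 0).
#' @param labels optional binary 3D array of the same shape.
#' @return object of class \code{prost_volume}.
#' @export
prost_volume <- function(data, spacing = c(1, 1, 1), labels = NULL) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) stop("spacing must be positive")
  if (!is.null(labels)) {
    if (!identical(dim(labels), dim(data))) stop("labels must match volume shape")
    if (!all(labels %in% c(0, 1))) stop("labels must be binary")
    storage.mode(labels) <- "double"
  }
  structure(list(data = data, spacing = spacing, labels = labels),
            class = "prost_volume")
}

#' @export
print.prost_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<prost_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm%s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              if (is.null(x$labels)) "" else
                sprintf(", labels (%d fg voxels)", sum(x$labels > 0))))
  invisible(x)
}

#' @export
dim.prost_volume <- function(x) dim(x$data)

as_volume <- function(x, spacing = c(1, 1, 1)) {
  if (inherits(x, "prost_volume")) x else prost_volume(x, spacing)
}

#' World coordinates of every voxel centre
#'
#' @param dim integer(3) grid size.
#' @param spacing numeric(3) spacing in mm.
#' @return matrix (prod(dim) x 3) of world mm coordinates, voxel (1,1,1) first,
#'   axis 1 fastest (R array order).
#' @export
voxel_world_coords <- function(dim, spacing = c(1, 1, 1)) {
  dim <- as.integer(dim); spacing <- rep_len(as.numeric(spacing), 3L)
  ctr <- (dim + 1) / 2
  x <- (seq_len(dim[1]) - ctr[1]) * spacing[1]
  y <- (seq_len(dim[2]) - ctr[2]) * spacing[2]
  z <- (seq_len(dim[3]) - ctr[3]) * spacing[3]
  cbind(rep(x, times = dim[2] * dim[3]),
        rep(rep(y, each = dim[1]), times = dim[3]),
        rep(z, each = dim[1] * dim[2]))
}

world_to_index <- function(w, dim, spacing) {
  ctr <- (dim + 1) / 2
  cbind(w[, 1] / spacing[1] + ctr[1],
        w[, 2] / spacing[2] + ctr[2],
        w[, 3] / spacing[3] + ctr[3])
}

index_to_world <- function(idx, dim, spacing) {
  ctr <- (dim + 1) / 2
  cbind((idx[, 1] - ctr[1]) * spacing[1],
        (idx[, 2] - ctr[2]) * spacing[2],
        (idx[, 3] - ctr[3]) * spacing[3])
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers around \pkg{RNifti}.  Spacing is taken from / written to the
#' NIfTI pixdim; the volume is treated as centred on the isocentre regardless
#' of any stored origin.
#'
#' @param path file path (.nii or .nii.gz).
#' @param vol a \code{prost_volume}.
#' @return \code{read_volume} returns a \code{prost_volume};
#'   \code{write_volume} returns \code{path} invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1, drop = TRUE]
  prost_volume(a, spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  vol <- as_volume(vol)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a dense displacement field as 3-channel NIfTI
#'
#' Displacements are stored in mm, backward convention (the output voxel at x
#' samples the input at x + u(x)); the convention is recorded in the NIfTI
#' description field.
#'
#' @param field 4D array (nx, ny, nz, 3) of mm displacements.
#' @param spacing numeric(3) grid spacing in mm.
#' @inheritParams read_volume
#' @export
write_field <- function(field, spacing, path) {
  stopifnot(length(dim(field)) == 4L, dim(field)[4] == 3L)
  img <- RNifti::asNifti(field)
  RNifti::pixdim(img) <- c(spacing, 1)
  img$descrip <- "backward displacement field, mm"
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  stopifnot(length(dim(a)) == 4L, dim(a)[4] == 3L)
  list(field = a, spacing = RNifti::pixdim(img)[1:3])
}
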