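# Trilinear sampling kernel. Everything projective and every warp in the
# package reduces to this gather; its linearity in the voxel values is what
# makes ProST/inv-ProST and the dense warps differentiable by construction.

# Gather arr at continuous 1-based indices idx (m x 3).
# arr: (n1,n2,n3) or (n1,n2,n3,C). mode "zero": out-of-support samples are 0;
# mode "edge": indices clamped to the grid (used for displacement-field
# composition so the flow does not see a spurious zero boundary).
# Returns list(values [m or m x C], and when want_info: corner linear index /
# weight matrices for the backward passes).
trilinear_kernel <- function(arr, idx, mode = c("zero", "edge"),
                             want_info = FALSE) {
  mode <- match.arg(mode)
  d <- dim(arr)
  nch <- if (length(d) == 4L) d[4] else 1L
  n1 <- d[1]; n2 <- d[2]; n3 <- d[3]
  m <- nrow(idx)

  x <- idx[, 1]; y <- idx[, 2]; z <- idx[, 3]
  if (mode == "edge") {
    x <- pmin(pmax(x, 1), n1); y <- pmin(pmax(y, 1), n2); z <- pmin(pmax(z, 1), n3)
  }
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0

  # corner validity per axis (zero mode: a corner outside contributes 0)
  in1a <- x0 >= 1 & x0 <= n1; in1b <- x0 + 1 >= 1 & x0 + 1 <= n1
  in2a <- y0 >= 1 & y0 <= n2; in2b <- y0 + 1 >= 1 & y0 + 1 <= n2
  in3a <- z0 >= 1 & z0 <= n3; in3b <- z0 + 1 >= 1 & z0 + 1 <= n3

  wx <- cbind(1 - fx, fx); wy <- cbind(1 - fy, fy); wz <- cbind(1 - fz, fz)
  okx <- cbind(in1a, in1b); oky <- cbind(in2a, in2b); okz <- cbind(in3a, in3b)
  cx <- cbind(pmin(pmax(x0, 1), n1), pmin(pmax(x0 + 1, 1), n1))
  cy <- cbind(pmin(pmax(y0, 1), n2), pmin(pmax(y0 + 1, 1), n2))
  cz <- cbind(pmin(pmax(z0, 1), n3), pmin(pmax(z0 + 1, 1), n3))

  nvox <- n1 * n2 * n3
  vals <- if (nch > 1L) matrix(0, m, nch) else numeric(m)
  if (want_info) {
    LIN <- matrix(1L, m, 8L)   # corner linear voxel index (clamped)
    W   <- matrix(0,  m, 8L)   # corner weight (0 where invalid in zero mode)
    CV  <- if (nch > 1L) NULL else matrix(0, m, 8L)  # corner values (1 channel)
  }
  arrm <- if (nch > 1L) matrix(arr, nvox, nch) else as.vector(arr)

  corner <- 0L
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
    corner <- corner + 1L
    w <- wx[, a] * wy[, b] * wz[, cc]
    ok <- okx[, a] & oky[, b] & okz[, cc]
    w <- w * ok
    lin <- cx[, a] + n1 * (cy[, b] - 1) + n1 * n2 * (cz[, cc] - 1)
    if (nch > 1L) {
      vals <- vals + arrm[lin, , drop = FALSE] * w
    } else {
      cv <- arrm[lin]
      vals <- vals + cv * w
      if (want_info) CV[, corner] <- cv * ok
    }
    if (want_info) { LIN[, corner] <- lin; W[, corner] <- w }
  }

  if (!want_info) return(list(values = vals))
  list(values = vals, lin = LIN, w = W, cv = if (nch == 1L) CV else NULL,
       frac = cbind(fx, fy, fz), okx = okx, oky = oky, okz = okz,
       wx = wx, wy = wy, wz = wz, cx = cx, cy = cy, cz = cz, dim = d)
}

# Scatter-add of per-sample corner contributions into a voxel grid.
# g: m (or m x C) upstream gradient; info from trilinear_kernel(want_info=TRUE).
trilinear_backward_values <- function(info, g) {
  d <- info$dim
  nvox <- d[1] * d[2] * d[3]
  nch <- if (length(d) == 4L) d[4] else 1L
  idx <- as.vector(info$lin)
  if (nch == 1L) {
    contrib <- as.vector(info$w * g)
    out <- scatter_add(nvox, idx, contrib)
    array(out, d)
  } else {
    gm <- matrix(0, nvox, nch)
    for (ch in seq_len(nch)) {
      contrib <- as.vector(info$w * g[, ch])
      gm[, ch] <- scatter_add(nvox, idx, contrib)
    }
    array(gm, d)
  }
}

scatter_add <- function(n, idx, vals) {
  keep <- vals != 0
  if (!any(keep)) return(numeric(n))
  as.vector(Matrix::sparseMatrix(i = idx[keep], j = rep.int(1L, sum(keep)),
                                 x = vals[keep], dims = c(n, 1)))
}

# d(sampled value)/d(continuous index), per sample point: m x 3 (or per
# channel, summed against upstream gradient g). Single- and multi-channel.
trilinear_backward_coords <- function(arr, info, g) {
  d <- info$dim
  nch <- if (length(d) == 4L) d[4] else 1L
  wx <- info$wx; wy <- info$wy; wz <- info$wz
  okx <- info$okx; oky <- info$oky; okz <- info$okz
  nvox <- d[1] * d[2] * d[3]
  arrm <- if (nch > 1L) matrix(arr, nvox, nch) else as.vector(arr)
  m <- nrow(info$lin)
  gx <- numeric(m); gy <- numeric(m); gz <- numeric(m)
  corner <- 0L
  sgn <- c(-1, 1)
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
    corner <- corner + 1L
    ok <- okx[, a] & oky[, b] & okz[, cc]
    lin <- info$lin[, corner]
    if (nch > 1L) {
      cv_g <- rowSums(arrm[lin, , drop = FALSE] * g) * ok
    } else {
      cv_g <- arrm[lin] * g * ok
    }
    gx <- gx + cv_g * sgn[a] * wy[, b] * wz[, cc]
    gy <- gy + cv_g * wx[, a] * sgn[b] * wz[, cc]
    gz <- gz + cv_g * wx[, a] * wy[, b] * sgn[cc]
  }
  cbind(gx, gy, gz)
}

#' Trilinear interpolation of a volume at world coordinates
#'
#' Values are interpolated trilinearly; points outside the volume support
#' return 0.  This sampling primitive realises every resampling ("composition")
#' operation in the projective transforms and warps.
#'
#' @param vol a \code{prost_volume} (or 3D array with unit spacing).
#' @param coords matrix (m x 3) of world coordinates in mm.
#' @return numeric(m) interpolated values.
#' @export
resample_trilinear <- function(vol, coords) {
  vol <- as_volume(vol)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  idx <- world_to_index(coords, dim(vol$data), vol$spacing)
  unname(trilinear_kernel(vol$data, idx)$values)
}
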