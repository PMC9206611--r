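# Minimal reverse-mode automatic differentiation tape.
#
# The registration network needs gradients through 2D/3D convolutions,
# batch normalisation, the ProST/inv-ProST sampling operators, the affine
# warp (including coordinate gradients w.r.t. the 7 pose parameters) and the
# scaling-and-squaring integration.  All of these are compositions of gathers,
# linear maps and sums, so a small tape suffices.  Convolutions are im2col +
# BLAS matrix products; sampling backward passes are sparse scatter-adds.
#
# Values are plain numeric arrays, channels last: 2D maps (h, w, c), 3D maps
# (d1, d2, d3, c).  Batch size is always 1 (as in the training regime the
# network is designed for), so batch normalisation normalises each channel
# over its spatial locations.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tp_node <- function(tp, val, parents = integer(), back = NULL) {
  force(val)                       # promises may append nodes to the tape:
  parents <- as.integer(parents)   # force both before reading the counter
  n <- tp$n + 1L
  if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- list(val = val, parents = parents, back = back)
  tp$n <- n
  n
}

tp_val <- function(tp, id) {
  id <- as.integer(id)   # force: id may be a promise that appends to the tape
  tp$nodes[[id]]$val
}

tp_const <- function(tp, val) tp_node(tp, val)

# Backward sweep from the (scalar) node `loss`; returns a list of gradients
# indexed by node id (NULL where no gradient flows).
tp_backward <- function(tp, loss) {
  n <- tp$n
  grads <- vector("list", n)
  grads[[loss]] <- 1
  for (i in seq(n, 1L)) {
    g <- grads[[i]]
    nd <- tp$nodes[[i]]
    if (is.null(g) || is.null(nd$back)) next
    pg <- nd$back(g)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[k]
      if (is.null(pg[[k]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}

tp_add <- function(tp, a, b) {
  tp_node(tp, tp_val(tp, a) + tp_val(tp, b), c(a, b),
          function(g) list(g, g))
}

tp_scale <- function(tp, a, s) {
  tp_node(tp, tp_val(tp, a) * s, a, function(g) list(g * s))
}

tp_tanh_scale <- function(tp, a, scale) {
  x <- tp_val(tp, a)
  th <- tanh(x)
  tp_node(tp, scale * th, a, function(g) list(g * scale * (1 - th^2)))
}

tp_leaky_relu <- function(tp, a, alpha = 0.2) {
  x <- tp_val(tp, a)
  m <- ifelse(x > 0, 1, alpha)
  tp_node(tp, x * m, a, function(g) list(g * m))
}

tp_reshape <- function(tp, a, new_dim) {
  x <- tp_val(tp, a)
  old_dim <- dim(x)
  y <- if (is.null(new_dim)) as.vector(x) else array(x, new_dim)
  tp_node(tp, y, a, function(g) {
    list(if (is.null(old_dim)) as.vector(g) else array(g, old_dim))
  })
}

# concatenate along the last (channel) axis; all inputs share spatial dims
tp_concat <- function(tp, ids) {
  vals <- lapply(ids, function(i) tp_val(tp, i))
  dims <- lapply(vals, dim)
  nd <- length(dims[[1]])
  chs <- vapply(dims, function(d) d[nd], numeric(1))
  sp <- dims[[1]][-nd]
  flat <- lapply(vals, function(v) matrix(v, prod(sp), ncol = dim(v)[nd]))
  y <- array(do.call(cbind, flat), c(sp, sum(chs)))
  ends <- cumsum(chs); starts <- c(1, head(ends, -1) + 1)
  tp_node(tp, y, as.integer(ids), function(g) {
    gm <- matrix(g, prod(sp), sum(chs))
    lapply(seq_along(ids), function(k)
      array(gm[, starts[k]:ends[k], drop = FALSE], dims[[k]]))
  })
}

# ---- dense -----------------------------------------------------------------

tp_dense <- function(tp, x, W, b) {
  xv <- as.vector(tp_val(tp, x))
  Wv <- tp_val(tp, W); bv <- tp_val(tp, b)
  y <- as.vector(Wv %*% xv + bv)
  tp_node(tp, y, c(x, W, b), function(g) {
    g <- as.vector(g)
    list(as.vector(crossprod(Wv, g)), outer(g, xv), g)
  })
}

# ---- convolutions ----------------------------------------------------------

.prostreg_cache <- new.env(parent = emptyenv())

cache_get <- function(key, make) {
  v <- .prostreg_cache[[key]]
  if (is.null(v)) {
    v <- make()
    assign(key, v, envir = .prostreg_cache)
  }
  v
}

# im2col index table for an N-D convolution with 'same'-style padding.
# sp: spatial dims; k: kernel sizes; cin channels; stride per axis.
# Returns list(idx [n_out x prod(k)*cin], pad, out_sp, pdim).
im2col_plan <- function(sp, k, cin, stride) {
  nd <- length(sp)
  pad_lo <- (k - 1L) %/% 2L
  pad_hi <- k - 1L - pad_lo
  pdim <- sp + pad_lo + pad_hi
  out_sp <- (sp + stride - 1L) %/% stride     # ceiling(sp / stride)
  # output position -> top-left corner in padded coords
  starts <- lapply(seq_len(nd), function(a) (seq_len(out_sp[a]) - 1L) * stride[a] + 1L)
  corner <- as.matrix(do.call(expand.grid, starts))   # n_out x nd
  offs <- as.matrix(do.call(expand.grid, lapply(k, function(ki) 0:(ki - 1L))))
  n_out <- nrow(corner); n_off <- nrow(offs)
  lin_sp <- matrix(0L, n_out, n_off)
  mult <- cumprod(c(1L, pdim[-nd]))
  for (a in seq_len(nd)) {
    lin_sp <- lin_sp + outer(corner[, a] - 1L, offs[, a], "+") * mult[a]
  }
  lin_sp <- lin_sp + 1L
  ch_off <- (seq_len(cin) - 1L) * prod(pdim)
  idx <- matrix(0L, n_out, n_off * cin)
  for (ch in seq_len(cin)) {
    idx[, ((ch - 1L) * n_off + 1L):(ch * n_off)] <- lin_sp + ch_off[ch]
  }
  list(idx = idx, pad_lo = pad_lo, pdim = pdim, out_sp = out_sp,
       patch_len = n_off * cin)
}

pad_array <- function(x, sp, cin, pad_lo, pdim) {
  xp <- array(0, c(pdim, cin))
  nd <- length(sp)
  idx <- lapply(seq_len(nd), function(a) pad_lo[a] + seq_len(sp[a]))
  if (nd == 2L) xp[idx[[1]], idx[[2]], ] <- x
  else xp[idx[[1]], idx[[2]], idx[[3]], ] <- x
  xp
}

crop_array <- function(xp, sp, cin, pad_lo) {
  nd <- length(sp)
  idx <- lapply(seq_len(nd), function(a) pad_lo[a] + seq_len(sp[a]))
  if (nd == 2L) xp[idx[[1]], idx[[2]], , drop = FALSE]
  else xp[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
}

# General N-D conv (nd = 2 or 3). W node value: matrix (prod(k)*cin, cout);
# b node value: numeric(cout).
tp_conv <- function(tp, x, W, b, k, stride) {
  xv <- tp_val(tp, x)
  d <- dim(xv); nd <- length(d) - 1L
  sp <- d[seq_len(nd)]; cin <- d[nd + 1L]
  k <- as.integer(rep_len(k, nd)); stride <- as.integer(rep_len(stride, nd))
  key <- paste("conv", nd, paste(sp, collapse = "x"), paste(k, collapse = "x"),
               cin, paste(stride, collapse = "x"), sep = "_")
  plan <- cache_get(key, function() im2col_plan(sp, k, cin, stride))
  xp <- pad_array(xv, sp, cin, plan$pad_lo, plan$pdim)
  patches <- xp[plan$idx]
  dim(patches) <- dim(plan$idx)
  Wv <- tp_val(tp, W); bv <- tp_val(tp, b)
  y <- patches %*% Wv
  y <- sweep(y, 2, bv, "+")
  cout <- length(bv)
  yv <- array(y, c(plan$out_sp, cout))
  tp_node(tp, yv, c(x, W, b), function(g) {
    gm <- matrix(g, nrow(patches), cout)
    dW <- crossprod(patches, gm)
    db <- colSums(gm)
    if (all(stride == 1L) && all(k %% 2L == 1L)) {
      # dx by transposed convolution: correlate the output gradient with the
      # flipped kernel (exact for odd kernels with symmetric same-padding);
      # avoids a huge scatter-add
      tkey <- paste("convT", nd, paste(sp, collapse = "x"),
                    paste(k, collapse = "x"), cout, sep = "_")
      tplan <- cache_get(tkey, function() im2col_plan(sp, k, cout, rep(1L, nd)))
      gp <- pad_array(array(gm, c(sp, cout)), sp, cout, tplan$pad_lo, tplan$pdim)
      gpatch <- gp[tplan$idx]
      dim(gpatch) <- dim(tplan$idx)
      n_off <- prod(k)
      A <- array(Wv, c(n_off, cin, cout))
      Wt <- matrix(aperm(A[rev(seq_len(n_off)), , , drop = FALSE], c(1, 3, 2)),
                   n_off * cout, cin)
      dx <- gpatch %*% Wt
      list(array(dx, d), dW, db)
    } else {
      dpatch <- gm %*% t(Wv)
      npad <- prod(plan$pdim) * cin
      dxp <- scatter_add(npad, as.vector(plan$idx), as.vector(dpatch))
      dx <- crop_array(array(dxp, c(plan$pdim, cin)), sp, cin, plan$pad_lo)
      list(array(dx, d), dW, db)
    }
  })
}

# ---- batch normalisation (batch of one: per-channel over spatial dims) -----

tp_batchnorm <- function(tp, x, gamma, beta, eps = 1e-5) {
  xv <- tp_val(tp, x)
  d <- dim(xv); nd <- length(d) - 1L
  C <- d[nd + 1L]; N <- prod(d[seq_len(nd)])
  xm <- matrix(xv, N, C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  va <- colMeans(xc^2)
  sd_ <- sqrt(va + eps)
  xhat <- sweep(xc, 2, sd_, "/")
  gv <- tp_val(tp, gamma); bv <- tp_val(tp, beta)
  y <- sweep(sweep(xhat, 2, gv, "*"), 2, bv, "+")
  tp_node(tp, array(y, d), c(x, gamma, beta), function(g) {
    gm <- matrix(g, N, C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxhat <- sweep(gm, 2, gv, "*")
    # dx = (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) / sd
    t1 <- sweep(dxhat, 2, colMeans(dxhat))
    t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), "*")
    dx <- sweep(t1 - t2, 2, sd_, "/")
    list(array(dx, d), dgamma, dbeta)
  })
}

# ---- pooling / resizing ----------------------------------------------------

tp_avgpool2d <- function(tp, x) {
  xv <- tp_val(tp, x)
  d <- dim(xv)
  h <- d[1] %/% 2L; w <- d[2] %/% 2L; C <- d[3]
  xr <- array(xv[seq_len(2L * h), seq_len(2L * w), , drop = FALSE], c(2L, h, 2L, w, C))
  y <- (xr[1, , 1, , , drop = FALSE] + xr[2, , 1, , , drop = FALSE] +
          xr[1, , 2, , , drop = FALSE] + xr[2, , 2, , , drop = FALSE]) / 4
  y <- array(y, c(h, w, C))
  tp_node(tp, y, x, function(g) {
    gx <- array(0, d)
    gq <- array(g / 4, c(h, w, C))
    for (a in 1:2) for (b in 1:2)
      gx[seq(a, 2L * h, by = 2L), seq(b, 2L * w, by = 2L), ] <-
        gx[seq(a, 2L * h, by = 2L), seq(b, 2L * w, by = 2L), , drop = FALSE] + gq
    list(gx)
  })
}

# nearest-neighbour upsampling of a 3D feature map by integer factors
tp_upsample3d <- function(tp, x, f) {
  xv <- tp_val(tp, x)
  d <- dim(xv); f <- as.integer(rep_len(f, 3L))
  i1 <- rep(seq_len(d[1]), each = f[1])
  i2 <- rep(seq_len(d[2]), each = f[2])
  i3 <- rep(seq_len(d[3]), each = f[3])
  y <- xv[i1, i2, i3, , drop = FALSE]
  tp_node(tp, y, x, function(g) {
    # sum-pool the gradient back by factors f (strided-offset accumulation)
    gs <- array(0, d)
    for (a in seq_len(f[1])) for (b in seq_len(f[2])) for (cc in seq_len(f[3]))
      gs <- gs + g[seq(a, by = f[1], length.out = d[1]),
                   seq(b, by = f[2], length.out = d[2]),
                   seq(cc, by = f[3], length.out = d[3]), , drop = FALSE]
    list(gs)
  })
}

# copy a 2D map (h, w, c) m times along a new third (ray) axis -> (h, w, m, c)
tp_repeat_ray <- function(tp, x, m) {
  xv <- tp_val(tp, x)
  d <- dim(xv)
  y <- aperm(array(xv, c(d[1], d[2], d[3], m)), c(1, 2, 4, 3))
  tp_node(tp, y, x, function(g) {
    list(array(rowSums(matrix(aperm(g, c(1, 2, 4, 3)), prod(d), m)), d))
  })
}

# ---- sampling (the differentiable spatial transforms) ----------------------

# vol: node, value 3D array or 4D (multi-channel); idx: node or constant
# matrix (m x 3) of continuous 1-based voxel indices.
tp_sample <- function(tp, vol, idx, mode = "zero") {
  idx_is_node <- is.numeric(idx) && length(idx) == 1L && idx == round(idx) &&
    idx >= 1 && idx <= tp$n && is.null(dim(idx))
  if (idx_is_node) {
    iv <- tp_val(tp, idx)
    parents <- c(vol, as.integer(idx))
  } else {
    iv <- idx
    parents <- vol
  }
  vv <- tp_val(tp, vol)
  info <- trilinear_kernel(vv, iv, mode = mode, want_info = TRUE)
  tp_node(tp, info$values, parents, function(g) {
    dvol <- trilinear_backward_values(info, g)
    if (idx_is_node) {
      didx <- trilinear_backward_coords(vv, info, g)
      list(dvol, didx)
    } else list(dvol)
  })
}

# multiply by a constant (mask) elementwise
tp_mask <- function(tp, x, m) {
  tp_node(tp, tp_val(tp, x) * m, x, function(g) list(g * m))
}

# min-max normalise to [0,1]; the range is treated as a constant of the
# forward pass (straight-through), which is exact almost everywhere.
tp_normalise01 <- function(tp, x) {
  xv <- tp_val(tp, x)
  rng <- range(xv)
  s <- rng[2] - rng[1]
  if (s <= 0) return(tp_scale(tp, x, 0))
  tp_node(tp, (xv - rng[1]) / s, x, function(g) list(g / s))
}

# sum a beam-space node (Sx, Sy, K) over the ray axis, times spacing
tp_ray_sum <- function(tp, x, spacing_mm = 1) {
  xv <- tp_val(tp, x)
  d <- dim(xv)
  y <- matrix(rowSums(matrix(xv, d[1] * d[2], d[3])), d[1], d[2]) * spacing_mm
  tp_node(tp, y, x, function(g) {
    list(array(rep(as.vector(g) * spacing_mm, times = d[3]), d))
  })
}

# ---- affine pose ops --------------------------------------------------------

rot_derivs <- function(rotation) {
  r <- rotation * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1]); cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  dRx <- matrix(c(0, 0, 0, 0, -sx, cx, 0, -cx, -sx), 3, 3)
  dRy <- matrix(c(-sy, 0, -cy, 0, 0, 0, cy, 0, -sy), 3, 3)
  dRz <- matrix(c(-sz, cz, 0, -cz, -sz, 0, 0, 0, 0), 3, 3)
  deg <- pi / 180
  list(R = Rz %*% Ry %*% Rx,
       dR = list(deg * (Rz %*% Ry %*% dRx),
                 deg * (Rz %*% dRy %*% Rx),
                 deg * (dRz %*% Ry %*% Rx)))
}

# Sampling coordinates (voxel indices) of the backward affine warp:
# idx = index( T(p)^{-1} pts ), pts world mm (constant matrix or node).
# Gradient flows to the 7 pose parameters and, if pts is a node, to pts.
tp_affine_warp_coords <- function(tp, p, pts, grid_dim, spacing) {
  pv <- tp_val(tp, p)
  pts_is_node <- length(pts) == 1L && is.null(dim(pts))
  P <- if (pts_is_node) tp_val(tp, pts) else pts
  rd <- rot_derivs(pv[1:3])
  s <- exp(pv[7])
  tvec <- pv[4:6]
  Pt <- sweep(P, 2, tvec)
  Y <- (Pt %*% rd$R) / s              # rows are R^T (x - t) / s
  idx <- world_to_index(Y, grid_dim, spacing)
  parents <- if (pts_is_node) c(p, pts) else p
  tp_node(tp, idx, parents, function(g) {
    gw <- g
    gw[, 1] <- gw[, 1] / spacing[1]; gw[, 2] <- gw[, 2] / spacing[2]
    gw[, 3] <- gw[, 3] / spacing[3]
    dp <- numeric(7)
    for (k in 1:3) dp[k] <- sum(gw * (Pt %*% rd$dR[[k]])) / s
    # dY/dt = -R^T / s  ->  grad_t = -(1/s) R %*% colSums(gw)
    dp[4:6] <- -(rd$R %*% colSums(gw)) / s
    dp[7] <- -sum(gw * Y)
    if (pts_is_node) {
      # dY/dpts = R^T / s -> grad rows: (1/s) R gw_i  = gw %*% R^T... rows
      dpts <- (gw %*% t(rd$R)) / s
      list(dp, dpts)
    } else list(dp)
  })
}

# displacement field (n x 3, mm) -> sampling voxel indices base + u/spacing
tp_field_coords <- function(tp, u, grid_dim, spacing) {
  uv <- tp_val(tp, u)
  base <- cache_get(paste0("base_", paste(grid_dim, collapse = "x")),
                    function() base_index_grid(grid_dim))
  idx <- base
  idx[, 1] <- idx[, 1] + uv[, 1] / spacing[1]
  idx[, 2] <- idx[, 2] + uv[, 2] / spacing[2]
  idx[, 3] <- idx[, 3] + uv[, 3] / spacing[3]
  tp_node(tp, idx, u, function(g) {
    g[, 1] <- g[, 1] / spacing[1]; g[, 2] <- g[, 2] / spacing[2]
    g[, 3] <- g[, 3] / spacing[3]
    list(g)
  })
}

# world points x + u(x) from a displacement node (n x 3, mm)
tp_displaced_points <- function(tp, u, grid_dim, spacing) {
  W <- cache_get(paste0("world_", paste(grid_dim, collapse = "x"), "_",
                        paste(signif(spacing, 8), collapse = "x")),
                 function() index_to_world(base_index_grid(grid_dim), grid_dim, spacing))
  uv <- tp_val(tp, u)
  tp_node(tp, W + uv, u, function(g) list(g))
}

# scaling-and-squaring on the tape; v node: (n x 3) mm velocity matrix
tp_integrate_velocity <- function(tp, v, n_steps, grid_dim, spacing) {
  u <- tp_scale(tp, v, 1 / 2^n_steps)
  for (s in seq_len(n_steps)) {
    u_arr <- tp_reshape(tp, u, c(grid_dim, 3L))
    idx <- tp_field_coords(tp, u, grid_dim, spacing)
    delta <- tp_sample(tp, u_arr, idx, mode = "edge")
    u <- tp_add(tp, u, delta)
  }
  u
}

# ---- losses -----------------------------------------------------------------

# global zero-normalised cross-correlation between node a and constant b over
# a constant logical mask (vectors)
tp_ncc <- function(tp, a, b, mask = NULL) {
  av <- as.vector(tp_val(tp, a))
  bv <- as.vector(b)
  if (is.null(mask)) mask <- rep(TRUE, length(av))
  m <- as.vector(mask)
  n <- sum(m)
  A <- av[m] - mean(av[m])
  B <- bv[m] - mean(bv[m])
  sa <- sqrt(sum(A^2)); sb <- sqrt(sum(B^2))
  if (sa <= 1e-12 || sb <= 1e-12) {
    warning("zero-variance input to NCC; returning 0")
    return(tp_node(tp, 0, a, function(g) {
      z <- tp_val(tp, a)
      list(z * 0)
    }))
  }
  val <- sum(A * B) / (sa * sb)
  tp_node(tp, val, a, function(g) {
    dA <- B / (sa * sb) - val * A / sa^2
    dA <- dA - mean(dA)                       # through the mean subtraction
    ga <- numeric(length(av))
    ga[m] <- g * dA
    orig <- tp_val(tp, a)
    list(if (is.null(dim(orig))) ga else array(ga, dim(orig)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean squared forward-difference gradient of a displacement node
# (n x 3 matrix over grid_dim), summed over the 3 channels
tp_smoothness <- function(tp, u, grid_dim) {
  uv <- tp_val(tp, u)
  d <- grid_dim
  nvox <- prod(d)
  val <- 0
  diffs <- vector("list", 9)
  k <- 0L
  for (ch in 1:3) {
    ua <- array(uv[, ch], d)
    for (ax in 1:3) {
      k <- k + 1L
      dd <- switch(ax,
                   ua[2:d[1], , , drop = FALSE] - ua[1:(d[1] - 1), , , drop = FALSE],
                   ua[, 2:d[2], , drop = FALSE] - ua[, 1:(d[2] - 1), , drop = FALSE],
                   ua[, , 2:d[3], drop = FALSE] - ua[, , 1:(d[3] - 1), drop = FALSE])
      diffs[[k]] <- dd
      val <- val + sum(dd^2)
    }
  }
  val <- val / nvox
  tp_node(tp, val, u, function(g) {
    gu <- matrix(0, nvox, 3)
    k <- 0L
    for (ch in 1:3) {
      ga <- array(0, d)
      for (ax in 1:3) {
        k <- k + 1L
        dd <- diffs[[k]] * (2 * g / nvox)
        if (ax == 1) {
          ga[2:d[1], , ] <- ga[2:d[1], , ] + dd
          ga[1:(d[1] - 1), , ] <- ga[1:(d[1] - 1), , ] - dd
        } else if (ax == 2) {
          ga[, 2:d[2], ] <- ga[, 2:d[2], ] + dd
          ga[, 1:(d[2] - 1), ] <- ga[, 1:(d[2] - 1), ] - dd
        } else {
          ga[, , 2:d[3]] <- ga[, , 2:d[3]] + dd
          ga[, , 1:(d[3] - 1)] <- ga[, , 1:(d[3] - 1)] - dd
        }
      }
      gu[, ch] <- as.vector(ga)
    }
    list(gu)
  })
}
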