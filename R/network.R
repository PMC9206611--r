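#' Registration network configuration
#'
#' Assembles the full configuration of the two-stage registration network: an
#' affine module (dual 2D encoders over (atlas projection, radiograph) channel
#' pairs regressing 7 pose parameters) followed by a local module (per-view
#' U-shaped 2D-encoder/3D-decoder networks whose beam-space feature maps are
#' brought into physical space by inv-ProST and fused into a stationary
#' velocity field, integrated by scaling and squaring).
#'
#' Two presets are provided: \code{"tiny"} (32^3 volumes, 24 x 32 inputs,
#' K = 32, decoder [16, 16, 8], M = 2 -- every mechanism of the full design,
#' CPU-trainable in minutes; the default) and \code{"full"} (192 x 128 x 192
#' volumes, 160 x 224 inputs, decoder [64, 32, 32, 16, 16, 16], M = 4).
#' Any field can be overridden.
#'
#' @param preset \code{"tiny"} (CPU-scale default) or \code{"full"} (publication-scale sizes).
#' @param ... named overrides of the fields listed below.
#' @return list of class \code{reg_config} with fields: \code{volume_dim},
#'   \code{spacing}, \code{input_px}, \code{k_samples}, \code{affine}
#'   (\code{num_levels}, \code{base_features}, \code{intermediate_concat}),
#'   \code{local} (\code{decoder_features}, \code{M}, \code{enc_base},
#'   \code{skip_connections}, \code{dual_decoders}, \code{use_inv_prost}),
#'   \code{integration_steps}, \code{delta}, \code{lr}, \code{epochs},
#'   \code{leaky_slope}.
#' @export
reg_config <- function(preset = c("tiny", "full"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "tiny") {
    list(volume_dim = c(32L, 32L, 32L), spacing = c(1, 1, 1),
         input_px = c(24L, 32L), k_samples = 32L,
         affine = list(num_levels = 3L, base_features = 8L,
                       intermediate_concat = TRUE,
                       output_scale = c(15, 15, 15, 6, 6, 6, 0.08)),
         local = list(decoder_features = c(16L, 16L, 8L), M = 2L,
                      enc_base = 8L, skip_connections = TRUE,
                      dual_decoders = TRUE, use_inv_prost = TRUE,
                      velocity_bound_mm = 8),
         integration_steps = 6L, delta = 0.01, lr = 1e-3, epochs = 8L,
         leaky_slope = 0.2, affine_loss_stride = 2L)
  } else {
    list(volume_dim = c(192L, 128L, 192L), spacing = c(0.664, 0.664, 1),
         input_px = c(160L, 224L), k_samples = 192L,
         affine = list(num_levels = 5L, base_features = 16L,
                       intermediate_concat = TRUE,
                       output_scale = c(20, 20, 20, 15, 15, 15, 0.15)),
         local = list(decoder_features = c(64L, 32L, 32L, 16L, 16L, 16L), M = 4L,
                      enc_base = 16L, skip_connections = TRUE,
                      dual_decoders = TRUE, use_inv_prost = TRUE,
                      velocity_bound_mm = 20),
         integration_steps = 7L, delta = 0.01, lr = 1e-5, epochs = 300L,
         leaky_slope = 0.2, affine_loss_stride = 2L)
  }
  ov <- list(...)
  for (nm in names(ov)) {
    if (nm %in% c("affine", "local")) cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    else cfg[[nm]] <- ov[[nm]]
  }
  if (any(cfg$input_px %% 2^cfg$affine$num_levels != 0))
    stop("input_px must be divisible by 2^num_levels of the affine encoder")
  class(cfg) <- "reg_config"
  cfg
}

# distribute an integer upsampling ratio over n steps (prime factors assigned
# round-robin to the step with the smallest current product)
factors_for <- function(ratio, n) {
  fs <- rep(1L, n)
  primes <- integer()
  r <- as.integer(ratio)
  p <- 2L
  while (r > 1L) {
    while (r %% p == 0L) { primes <- c(primes, p); r <- r %/% p }
    p <- p + 1L
  }
  for (pr in sort(primes, decreasing = TRUE)) {
    i <- which.min(fs)
    fs[i] <- fs[i] * pr
  }
  sort(fs, decreasing = TRUE)
}

# shape algebra of the local module: encoder depth, per-step upsampling
# factors, skip attachment levels, channel flow
local_plan <- function(cfg) {
  l <- cfg$local
  n_dec <- length(l$decoder_features)
  halvings <- function(n) { h <- 0L; while (n %% 2L == 0L && n %/% 2L >= 1L && h < 12L) { n <- n %/% 2L; h <- h + 1L }; h }
  n_enc <- min(n_dec, halvings(cfg$input_px[1]), halvings(cfg$input_px[2]))
  if (n_enc < 1L) stop("input size admits no encoder level")
  enc_feats <- l$enc_base * 2L^(seq_len(n_enc) - 1L)
  start_sp <- cfg$input_px %/% 2L^n_enc
  f1 <- factors_for(2L^n_enc, n_dec)
  f2 <- f1
  f3 <- factors_for(cfg$k_samples %/% l$M, n_dec)
  if (cfg$k_samples %% l$M != 0L)
    stop("k_samples must be a multiple of the stacking factor M")
  sp <- start_sp
  skip_level <- integer(n_dec); skip_ch <- integer(n_dec)
  for (s in seq_len(n_dec)) {
    sp <- sp * c(f1[s], f2[s])
    lvl <- n_enc - as.integer(round(log2(prod(f1[seq_len(s)]))))
    if (l$skip_connections && lvl >= 1L && all(cfg$input_px %/% 2L^lvl == sp)) {
      skip_level[s] <- lvl
      skip_ch[s] <- max(4L, l$decoder_features[s] %/% 2L)
    }
  }
  cin <- integer(n_dec)
  cin[1] <- enc_feats[n_enc] * (if (l$dual_decoders) 1L else 1L)
  if (n_dec > 1) for (s in 2:n_dec)
    cin[s] <- l$decoder_features[s - 1] + skip_ch[s - 1]
  list(n_enc = n_enc, enc_feats = enc_feats, start_sp = start_sp,
       fac = cbind(f1, f2, f3), skip_level = skip_level, skip_ch = skip_ch,
       cin = cin, n_dec = n_dec,
       out_ch = l$decoder_features[n_dec] + skip_ch[n_dec])
}

he_init <- function(nin, nout, k) {
  matrix(stats::rnorm(k * nin * nout, sd = sqrt(2 / (k * nin))), k * nin, nout)
}

add_conv_params <- function(P, name, k, cin, cout, bn = TRUE, sd = NULL) {
  P[[paste0(name, "_W")]] <- if (is.null(sd)) he_init(cin, cout, k)
    else matrix(stats::rnorm(k * cin * cout, sd = sd), k * cin, cout)
  P[[paste0(name, "_b")]] <- numeric(cout)
  if (bn) {
    P[[paste0(name, "_g")]] <- rep(1, cout)
    P[[paste0(name, "_be")]] <- numeric(cout)
  }
  P
}

#' Initialise the registration network
#'
#' Creates all trainable parameters: He-scaled normal convolution kernels,
#' unit-gain batch-norm, and narrow-normal (sd 1e-4) zero-bias weights for the
#' affine head and the velocity fusion convolution, so that the freshly
#' initialised network is close to the identity transform.
#'
#' @param cfg a \code{\link{reg_config}}.
#' @param seed integer seed for the weight draws.
#' @return object of class \code{prost_model}.
#' @export
init_registration_model <- function(cfg = reg_config(), seed = 1) {
  stopifnot(inherits(cfg, "reg_config"))
  with_seed(seed, {
    P <- list()
    a <- cfg$affine
    fa <- a$base_features * 2L^(seq_len(a$num_levels) - 1L)
    for (view in c("ap", "lat")) {
      cin <- 2L
      for (l in seq_len(a$num_levels)) {
        P <- add_conv_params(P, sprintf("aff_enc_%s_l%d", view, l), 9L, cin, fa[l])
        cin <- fa[l]
      }
    }
    if (a$intermediate_concat) {
      for (l in seq_len(a$num_levels)) {
        cin <- 2L * fa[l] + if (l > 1) fa[l - 1] else 0L
        P <- add_conv_params(P, sprintf("aff_comb_l%d", l), 9L, cin, fa[l])
      }
      head_ch <- fa[a$num_levels]
    } else head_ch <- 2L * fa[a$num_levels]
    hsp <- cfg$input_px %/% 2L^a$num_levels
    flat <- head_ch * prod(hsp)
    P$aff_head_W <- matrix(stats::rnorm(7L * flat, sd = 1e-4), 7L, flat)
    P$aff_head_b <- numeric(7L)

    lp <- local_plan(cfg)
    lcl <- cfg$local
    views <- if (lcl$dual_decoders) c("ap", "lat") else "sh"
    enc_views <- c("ap", "lat")
    for (view in enc_views) {
      cin <- 2L
      for (l in seq_len(lp$n_enc)) {
        P <- add_conv_params(P, sprintf("loc_enc_%s_l%d_a", view, l), 9L, cin, lp$enc_feats[l])
        P <- add_conv_params(P, sprintf("loc_enc_%s_l%d_b", view, l), 9L,
                             lp$enc_feats[l], lp$enc_feats[l])
        cin <- lp$enc_feats[l]
      }
    }
    if (!lcl$dual_decoders) {
      # per-level fusion convs of the shared (single-decoder) variant
      for (l in seq_len(lp$n_enc))
        P <- add_conv_params(P, sprintf("loc_comb_l%d", l), 9L,
                             2L * lp$enc_feats[l], lp$enc_feats[l])
    }
    for (view in views) {
      for (s in seq_len(lp$n_dec)) {
        P <- add_conv_params(P, sprintf("loc_dec_%s_s%d", view, s), 27L,
                             lp$cin[s], lcl$decoder_features[s], bn = FALSE)
        if (lp$skip_level[s] > 0L)
          P <- add_conv_params(P, sprintf("loc_skip_%s_s%d", view, s), 27L,
                               lp$enc_feats[lp$skip_level[s]], lp$skip_ch[s])
      }
    }
    fus_in <- lp$out_ch * length(views)
    P <- add_conv_params(P, "fusion", 27L, fus_in, 3L, bn = FALSE, sd = 1e-4)

    structure(list(config = cfg, params = P, plan = lp,
                   cache = new.env(parent = emptyenv())),
              class = "prost_model")
  })
}

#' @export
print.prost_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<prost_model> %s volume, %d x %d input, %s parameters%s\n",
              paste(x$config$volume_dim, collapse = "x"),
              x$config$input_px[1], x$config$input_px[2],
              format(np, big.mark = ","),
              if (is.null(x$history)) " (untrained)" else
                sprintf(" (trained %d epochs)", max(x$history$epoch))))
  invisible(x)
}

# geometry at the network input resolution (same field of view)
net_geometry <- function(geom, input_px) {
  f <- geom$detector_px / input_px
  projection_geometry(lao_rao_deg = geom$lao_rao_deg,
                      cranio_caudal_deg = geom$cranio_caudal_deg,
                      sdd_mm = geom$sdd_mm, iso_mm = geom$iso_mm,
                      detector_px = input_px, pixel_mm = geom$pixel_mm * f,
                      k_samples = geom$k_samples,
                      depth_window_mm = geom$depth_window_mm)
}

# cached geometry-derived constants for the forward pass
geom_constants <- function(model, geom) {
  cfg <- model$config
  g <- net_geometry(geom, cfg$input_px)
  key <- paste0("g_", signif(g$lao_rao_deg, 8), "_", signif(g$cranio_caudal_deg, 8),
                "_", g$k_samples, "_", signif(g$pixel_mm[1], 8))
  v <- model$cache[[key]]
  if (!is.null(v)) return(v)
  bg <- beam_grid(g)
  d <- dim(bg$coords)
  beam_idx <- world_to_index(matrix(bg$coords, prod(d[1:3]), 3),
                             cfg$volume_dim, cfg$spacing)
  ig <- inverse_grid(cfg$volume_dim, cfg$spacing, g)
  v <- list(geom = g, beam_idx = beam_idx, beam_dim = d[1:3],
            ray_mm = bg$spacing_mm,
            inv_idx = matrix(ig$coords, prod(cfg$volume_dim), 3),
            inv_mask = as.numeric(ig$mask))
  assign(key, v, envir = model$cache)
  v
}

# ---- forward pass ------------------------------------------------------------

conv_bn_act <- function(tp, x, pid, name, stride, slope, bn = TRUE, act = TRUE,
                        k = 3L) {
  y <- tp_conv(tp, x, pid(paste0(name, "_W")), pid(paste0(name, "_b")),
               k = k, stride = stride)
  if (bn) y <- tp_batchnorm(tp, y, pid(paste0(name, "_g")), pid(paste0(name, "_be")))
  if (act) y <- tp_leaky_relu(tp, y, slope)
  y
}

# Full differentiable forward pass; builds the tape and returns node ids.
forward_pass <- function(model, case, affine_only = FALSE, with_loss = TRUE) {
  cfg <- model$config
  sl <- cfg$leaky_slope
  lp <- model$plan
  vd <- cfg$volume_dim; sp <- cfg$spacing
  nvox <- prod(vd)
  atlas <- case$atlas
  stopifnot(identical(dim(atlas$data), as.integer(vd)))
  gc_ap <- geom_constants(model, case$geom_ap)
  gc_lat <- geom_constants(model, case$geom_lat)

  tp <- new_tape()
  pe <- new.env(parent = emptyenv())
  pid <- function(name) {
    id <- pe[[name]]
    if (is.null(id)) {
      w <- model$params[[name]]
      if (is.null(w)) stop("unknown parameter: ", name)
      id <- tp_const(tp, w)
      pe[[name]] <- id
    }
    id
  }

  atlasV <- tp_const(tp, atlas$data)
  # atlas projections for the affine module (constant w.r.t. the parameters):
  # cached per case geometry
  atlas_proj <- function(gc) {
    key <- paste0("aproj_", signif(gc$geom$lao_rao_deg, 8), "_",
                  signif(sum(atlas$data), 10))
    v <- model$cache[[key]]
    if (is.null(v)) {
      bv <- trilinear_kernel(atlas$data, gc$beam_idx)$values
      img <- matrix(rowSums(matrix(bv, prod(gc$beam_dim[1:2]), gc$beam_dim[3])),
                    gc$beam_dim[1], gc$beam_dim[2]) * gc$ray_mm
      v <- normalise01(img)
      assign(key, v, envir = model$cache)
    }
    v
  }
  in_ap <- tp_const(tp, array(c(atlas_proj(gc_ap), case$drr_ap),
                              c(cfg$input_px, 2L)))
  in_lat <- tp_const(tp, array(c(atlas_proj(gc_lat), case$drr_lat),
                               c(cfg$input_px, 2L)))

  # ---- affine module
  a <- cfg$affine
  enc <- list(ap = in_ap, lat = in_lat)
  lv <- list(ap = list(), lat = list())
  for (view in c("ap", "lat")) {
    x <- enc[[view]]
    for (l in seq_len(a$num_levels)) {
      x <- conv_bn_act(tp, x, pid, sprintf("aff_enc_%s_l%d", view, l), 2L, sl)
      lv[[view]][[l]] <- x
    }
  }
  if (a$intermediate_concat) {
    comb <- NULL
    for (l in seq_len(a$num_levels)) {
      ins <- c(lv$ap[[l]], lv$lat[[l]])
      if (!is.null(comb)) ins <- c(ins, tp_avgpool2d(tp, comb))
      comb <- conv_bn_act(tp, tp_concat(tp, ins), pid,
                          sprintf("aff_comb_l%d", l), 1L, sl)
    }
    head_in <- comb
  } else {
    head_in <- tp_concat(tp, c(lv$ap[[a$num_levels]], lv$lat[[a$num_levels]]))
  }
  # bounded pose outputs: scaled tanh keeps the regressed pose inside a
  # physically plausible range (the warp cannot throw the atlas out of the
  # grid), while zero-init weights still give an identity transform at start
  p <- tp_dense(tp, tp_reshape(tp, head_in, NULL), pid("aff_head_W"), pid("aff_head_b"))
  p <- tp_tanh_scale(tp, p, a$output_scale)

  # ---- affine warp of the atlas
  Wpts <- cache_get(paste0("world_", paste(vd, collapse = "x"), "_",
                           paste(signif(sp, 8), collapse = "x")),
                    function() index_to_world(base_index_grid(vd), vd, sp))
  # affine-only training evaluates the image term on a strided voxel subgrid:
  # the pose is a global 7-parameter quantity, so a subsampled NCC estimate
  # carries the same signal at a fraction of the sampling cost
  st <- cfg$affine_loss_stride
  use_stride <- affine_only && with_loss && !is.null(st) && st > 1L
  subsel <- NULL
  if (use_stride) {
    subsel <- cache_get(paste0("stride_", st, "_", paste(vd, collapse = "x")),
                        function() {
                          b <- base_index_grid(vd)
                          which(b[, 1] %% st == 1L & b[, 2] %% st == 1L &
                                  b[, 3] %% st == 1L)
                        })
    idxT <- tp_affine_warp_coords(tp, p, Wpts[subsel, , drop = FALSE], vd, sp)
  } else {
    idxT <- tp_affine_warp_coords(tp, p, Wpts, vd, sp)
  }
  warpT <- tp_sample(tp, atlasV, idxT)
  ids <- list(tape = tp, pe = pe, p = p, warp_affine = warpT)

  if (!affine_only) {
    warpT_arr <- tp_reshape(tp, warpT, vd)
    lcl <- cfg$local
    gcs <- list(ap = gc_ap, lat = gc_lat)
    drrs <- list(ap = case$drr_ap, lat = case$drr_lat)
    encmaps <- list()
    for (view in c("ap", "lat")) {
      gc <- gcs[[view]]
      bv <- tp_sample(tp, warpT_arr, gc$beam_idx)
      bimg <- tp_ray_sum(tp, tp_reshape(tp, bv, gc$beam_dim), gc$ray_mm)
      bimg <- tp_normalise01(tp, bimg)
      x <- tp_concat(tp, c(tp_reshape(tp, bimg, c(cfg$input_px, 1L)),
                           tp_const(tp, array(drrs[[view]], c(cfg$input_px, 1L)))))
      maps <- list()
      for (l in seq_len(lp$n_enc)) {
        x <- conv_bn_act(tp, x, pid, sprintf("loc_enc_%s_l%d_a", view, l), 2L, sl)
        x <- conv_bn_act(tp, x, pid, sprintf("loc_enc_%s_l%d_b", view, l), 1L, sl)
        maps[[l]] <- x
      }
      encmaps[[view]] <- maps
    }
    dec_views <- if (lcl$dual_decoders) c("ap", "lat") else "sh"
    if (!lcl$dual_decoders) {
      shared <- list()
      for (l in seq_len(lp$n_enc))
        shared[[l]] <- conv_bn_act(tp, tp_concat(tp, c(encmaps$ap[[l]], encmaps$lat[[l]])),
                                   pid, sprintf("loc_comb_l%d", l), 1L, sl)
      encmaps <- list(sh = shared)
    }
    phys <- list()
    for (view in dec_views) {
      maps <- encmaps[[view]]
      h <- tp_repeat_ray(tp, maps[[lp$n_enc]], lcl$M)
      ray_sz <- lcl$M
      for (s in seq_len(lp$n_dec)) {
        h <- tp_conv(tp, h, pid(sprintf("loc_dec_%s_s%d_W", view, s)),
                     pid(sprintf("loc_dec_%s_s%d_b", view, s)), k = 3L, stride = 1L)
        h <- tp_leaky_relu(tp, h, sl)
        h <- tp_upsample3d(tp, h, c(lp$fac[s, 1], lp$fac[s, 2], lp$fac[s, 3]))
        ray_sz <- ray_sz * lp$fac[s, 3]
        if (lp$skip_level[s] > 0L) {
          sk <- tp_repeat_ray(tp, maps[[lp$skip_level[s]]], ray_sz)
          sk <- conv_bn_act(tp, sk, pid, sprintf("loc_skip_%s_s%d", view, s), 1L, sl)
          h <- tp_concat(tp, c(h, sk))
        }
      }
      # beam axes are (in-plane 1, in-plane 2, ray): reorder to (Sx, Sy, K)
      gc <- gcs[[if (view == "sh") "ap" else view]]
      if (lcl$use_inv_prost) {
        v <- tp_sample(tp, h, gc$inv_idx)          # (nvox x C)
        v <- tp_mask(tp, v, gc$inv_mask)
        phys[[view]] <- tp_reshape(tp, v, c(vd, lp$out_ch))
      } else {
        # direct resampling of the beam-space map onto the volume grid
        bd <- gc$beam_dim
        key <- paste0("resize_", paste(bd, collapse = "x"), "_", paste(vd, collapse = "x"))
        ridx <- cache_get(key, function() {
          b <- base_index_grid(vd)
          cbind((b[, 1] - 0.5) / vd[1] * bd[1] + 0.5,
                (b[, 2] - 0.5) / vd[2] * bd[2] + 0.5,
                (b[, 3] - 0.5) / vd[3] * bd[3] + 0.5)
        })
        v <- tp_sample(tp, h, ridx, mode = "edge")
        phys[[view]] <- tp_reshape(tp, v, c(vd, lp$out_ch))
      }
    }
    fused <- if (length(phys) > 1L) tp_concat(tp, unlist(phys)) else phys[[1]]
    vel <- tp_conv(tp, fused, pid("fusion_W"), pid("fusion_b"), k = 3L, stride = 1L)
    # bounded velocity: keeps the integrated flow inside the grid even under
    # aggressive optimisation steps, and near zero it is the identity map of
    # the raw output (tanh'(0) = 1), preserving the near-identity init
    if (!is.null(lcl$velocity_bound_mm) && is.finite(lcl$velocity_bound_mm))
      vel <- tp_tanh_scale(tp, tp_scale(tp, vel, 1 / lcl$velocity_bound_mm),
                           lcl$velocity_bound_mm)   # b*tanh(x/b): slope 1 at 0
    vel <- tp_reshape(tp, vel, NULL)
    vel <- tp_node(tp, matrix(tp_val(tp, vel), nvox, 3L), vel,
                   function(g) list(as.vector(g)))
    phi <- tp_integrate_velocity(tp, vel, cfg$integration_steps, vd, sp)
    pts <- tp_displaced_points(tp, phi, vd, sp)
    idxPsi <- tp_affine_warp_coords(tp, p, pts, vd, sp)
    warpPsi <- tp_sample(tp, atlasV, idxPsi)
    ids$velocity <- vel; ids$phi <- phi; ids$warp_full <- warpPsi
    ids$idx_psi <- idxPsi
  }

  if (with_loss) {
    if (is.null(case$target)) stop("ground-truth target required for the loss")
    vf <- as.vector(case$target$data)
    # NCC over the whole volume: the images are already masked (background 0),
    # so the plain global statistic keeps a useful gradient even when the
    # warped atlas and the target barely overlap; restricting it to the
    # dilated target labels kills the signal as soon as overlap is lost
    mask <- NULL
    ncc1 <- tp_ncc(tp, ids$warp_affine, if (use_stride) vf[subsel] else vf, mask)
    loss <- tp_scale(tp, ncc1, -1)
    if (!affine_only) {
      ncc2 <- tp_ncc(tp, ids$warp_full, vf, mask)
      sm <- tp_smoothness(tp, ids$phi, vd)
      loss <- tp_add(tp, loss, tp_scale(tp, ncc2, -1))
      loss <- tp_add(tp, loss, tp_scale(tp, sm, cfg$delta))
      ids$ncc2 <- ncc2; ids$smooth <- sm
    }
    ids$ncc1 <- ncc1
    ids$loss <- loss
  }
  ids
}

#' Run the registration network on a case
#'
#' Inference entry point: regresses the affine pose, the velocity and local
#' deformation field phi, composes the total field Psi and warps the atlas
#' volume (trilinear) and labels (nearest neighbour).  Optionally writes the
#' five artefacts (warped volume/labels, phi, Psi as NIfTI; pose as JSON) to a
#' directory.
#'
#' @param model a \code{prost_model} (trained or not).
#' @param case a \code{registration_case} (ground truth not required).
#' @param out_dir optional output directory.
#' @param affine_only stop after the affine stage (phi = 0)?
#' @return object of class \code{registration_result}: \code{pose}
#'   (affine_params), \code{phi}, \code{psi} (4D mm fields),
#'   \code{warped_affine}, \code{warped_volume}, \code{warped_labels}.
#' @export
register_case <- function(model, case, out_dir = NULL, affine_only = FALSE) {
  cfg <- model$config
  vd <- cfg$volume_dim; sp <- cfg$spacing
  ids <- forward_pass(model, case, affine_only = affine_only, with_loss = FALSE)
  tp <- ids$tape
  pv <- tp_val(tp, ids$p)
  pose <- affine_params(pv[1:3], pv[4:6], pv[7])
  tmat <- affine_to_matrix(pose)
  phi <- if (affine_only) array(0, c(vd, 3L))
  else array(tp_val(tp, ids$phi), c(vd, 3L))
  psi <- compose_affine_local(tmat, phi, sp)
  atlas_lab <- prost_volume(case$atlas$data, sp, labels = case$atlas$labels)
  warped <- warp_dense(atlas_lab, psi)
  wa <- array(tp_val(tp, ids$warp_affine), vd)
  out <- structure(list(pose = pose, phi = phi, psi = psi,
                        warped_affine = prost_volume(wa, sp),
                        warped_volume = prost_volume(warped$data, sp),
                        warped_labels = warped$labels,
                        velocity = if (affine_only) NULL
                        else array(tp_val(tp, ids$velocity), c(vd, 3L))),
                   class = "registration_result")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_volume(out$warped_volume, file.path(out_dir, "warped_volume.nii.gz"))
    write_volume(prost_volume(out$warped_labels, sp),
                 file.path(out_dir, "warped_labels.nii.gz"))
    write_field(out$phi, sp, file.path(out_dir, "phi.nii.gz"))
    write_field(out$psi, sp, file.path(out_dir, "psi.nii.gz"))
    jsonlite::write_json(list(rotation = pose$rotation,
                              translation = pose$translation,
                              log_scale = pose$log_scale),
                         file.path(out_dir, "pose.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result>\n  ")
  print(x$pose)
  cat(sprintf("  local field: mean |phi| %.3f mm, max %.3f mm\n",
              mean(sqrt(rowSums(matrix(x$phi, length(x$phi) / 3, 3)^2))),
              max(sqrt(rowSums(matrix(x$phi, length(x$phi) / 3, 3)^2)))))
  invisible(x)
}
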