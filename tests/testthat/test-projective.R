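test_that("trilinear resampling is exact at voxel centres and linear between", {
  set.seed(1)
  a <- array(rnorm(5 * 6 * 7), c(5, 6, 7))
  vol <- prost_volume(a, c(1, 1, 1))
  idx <- cbind(c(2, 4), c(3, 5), c(4, 6))
  W <- prostreg:::index_to_world(idx, dim(a), c(1, 1, 1))
  expect_equal(resample_trilinear(vol, W), a[idx])

  # midpoint of two voxels is their average
  w1 <- prostreg:::index_to_world(cbind(2, 3, 4), dim(a), c(1, 1, 1))
  w2 <- prostreg:::index_to_world(cbind(3, 3, 4), dim(a), c(1, 1, 1))
  expect_equal(resample_trilinear(vol, (w1 + w2) / 2),
               (a[2, 3, 4] + a[3, 3, 4]) / 2)

  # constant volume: constant inside, zero outside
  cv <- prost_volume(array(3.5, c(4, 4, 4)))
  expect_equal(resample_trilinear(cv, cbind(0.2, -0.3, 0.1)), 3.5)
  expect_equal(resample_trilinear(cv, cbind(50, 0, 0)), 0)
})

test_that("ProST of a centred ball fills a run of ~2r along the central ray", {
  r <- 18
  vol <- ball_volume(48, r)
  g <- projection_geometry(detector_px = c(49, 49), pixel_mm = 1,
                           k_samples = 97, depth_window_mm = 60)
  b <- prost(vol, g)
  run_mm <- sum(b$values[25, 25, ] >= 0.5) * b$spacing_mm
  expect_lt(abs(run_mm - 2 * r), 2 * b$spacing_mm)

  # zero volume -> zero beam volume; linearity of the operator
  expect_true(all(prost(prost_volume(array(0, c(16, 16, 16))), g)$values == 0))
  set.seed(2)
  v1 <- array(rnorm(16^3), c(16, 16, 16)); v2 <- array(rnorm(16^3), c(16, 16, 16))
  lin <- prost(prost_volume(2 * v1 - 3 * v2), g)$values
  expect_equal(lin, 2 * prost(prost_volume(v1), g)$values -
                 3 * prost(prost_volume(v2), g)$values, tolerance = 1e-12)
})

test_that("spacing-scaled projection matches the analytic chord map of a ball", {
  r <- 24
  vol <- ball_volume(64, r)
  g <- projection_geometry(detector_px = c(97, 97), pixel_mm = 0.6,
                           k_samples = 160, depth_window_mm = 120)
  p <- drr(vol, g)
  oracle <- ball_chord_map(g, r)
  sel <- oracle$dist <= 0.9 * r
  rel <- abs(p$pixels[sel] - oracle$chord[sel]) / oracle$chord[sel]
  expect_lt(max(rel), 0.03)
  # a ray that misses the ball integrates to 0
  expect_equal(p$pixels[1, 1], 0)

  # Riemann refinement: doubling K leaves the scaled projection unchanged
  g2 <- projection_geometry(detector_px = c(97, 97), pixel_mm = 0.6,
                            k_samples = 320, depth_window_mm = 120)
  p2 <- drr(vol, g2)
  expect_lt(max(abs(p$pixels - p2$pixels)) / max(p$pixels), 0.01)
})

test_that("unscaled projection is the plain sum over ray samples", {
  vol <- ball_volume(32, 10)
  g <- projection_geometry(detector_px = c(33, 33), pixel_mm = 1,
                           k_samples = 48, depth_window_mm = 40)
  b <- prost(vol, g)
  p <- project(b, scaled = FALSE)
  expect_equal(p$pixels[17, 17], sum(b$values[17, 17, ]))
})

test_that("DRR of a sphere is symmetric; AP/LAT views separate along their axis", {
  vol <- ball_volume(32, 10)
  g <- projection_geometry(detector_px = c(33, 33), pixel_mm = 1,
                           k_samples = 64, depth_window_mm = 40)
  p <- drr(vol, g)$pixels
  expect_equal(which(p == max(p), arr.ind = TRUE)[1, ], c(row = 17, col = 17))
  expect_lt(max(abs(p - p[33:1, ])), 1e-9 + 0.02 * max(p))

  # two balls separated along the AP (y) axis superimpose in the AP view
  # and separate in the LAT view
  W <- voxel_world_coords(c(48, 48, 48), c(1, 1, 1))
  b2 <- pmin(pmax(6 - sqrt((W[, 1])^2 + (W[, 2] - 12)^2 + W[, 3]^2) + 0.5, 0), 1) +
    pmin(pmax(6 - sqrt((W[, 1])^2 + (W[, 2] + 12)^2 + W[, 3]^2) + 0.5, 0), 1)
  vol2 <- prost_volume(array(b2, c(48, 48, 48)))
  gap <- geometry_for_volume(vol2, detector_px = c(48, 48), k_samples = 64)
  glat <- geometry_for_volume(vol2, lao_rao_deg = 90, detector_px = c(48, 48),
                              k_samples = 64)
  pap <- drr(vol2, gap)$pixels; plat <- drr(vol2, glat)$pixels
  # AP: one blob (superimposed) => bright centre; LAT: centre is dark
  expect_gt(pap[24, 24] + pap[25, 25], 0)
  expect_lt(plat[24, 24] + plat[25, 25], 0.2 * max(plat))
})

test_that("inv-ProST approximately inverts ProST inside the cone, exactly 0 outside", {
  vol <- smooth_compact_volume(40, seed = 3)
  g <- projection_geometry(detector_px = c(96, 96), pixel_mm = 0.8,
                           k_samples = 80, depth_window_mm = sqrt(3) * 40)
  b <- prost(vol, g)
  ig <- inverse_grid(dim(vol$data), vol$spacing, g)
  rec <- inv_prost(b, ig)
  err <- (as.vector(rec$data) - as.vector(vol$data))[as.vector(ig$mask)]
  nrmse <- sqrt(mean(err^2)) / sqrt(mean(vol$data[ig$mask]^2))
  expect_lt(nrmse, 0.05)
  if (any(!ig$mask)) expect_true(all(rec$data[!ig$mask] == 0))

  # zero beam volume -> zero volume
  b0 <- b; b0$values <- b$values * 0
  expect_true(all(inv_prost(b0, ig)$data == 0))
  # geometry mismatch is an error
  g2 <- projection_geometry(lao_rao_deg = 10, detector_px = c(96, 96),
                            pixel_mm = 0.8, k_samples = 80,
                            depth_window_mm = sqrt(3) * 40)
  expect_error(inv_prost(b, inverse_grid(dim(vol$data), vol$spacing, g2)),
               "match")
})

test_that("prost/project/inv_prost equal their assembled linear operators", {
  # explicit matrix assembled by applying the operator to every basis volume
  n <- 8L
  g <- projection_geometry(detector_px = c(6, 6), pixel_mm = 2.2,
                           k_samples = 10, depth_window_mm = 16)
  nv <- n^3
  Mp <- matrix(0, 6 * 6 * 10, nv)
  for (i in seq_len(nv)) {
    e <- numeric(nv); e[i] <- 1
    Mp[, i] <- as.vector(prost(prost_volume(array(e, c(n, n, n))), g)$values)
  }
  set.seed(5)
  v <- rnorm(nv)
  bv <- prost(prost_volume(array(v, c(n, n, n))), g)
  expect_equal(as.vector(bv$values), as.vector(Mp %*% v), tolerance = 1e-9)
  ig <- inverse_grid(c(n, n, n), c(2, 2, 2), g)
  Mi <- matrix(0, nv, 6 * 6 * 10)
  for (i in seq_len(6 * 6 * 10)) {
    eb <- bv; eb$values <- array(0, dim(bv$values)); eb$values[i] <- 1
    Mi[, i] <- as.vector(inv_prost(eb, ig)$data)
  }
  expect_equal(as.vector(inv_prost(bv, ig)$data),
               as.vector(Mi %*% as.vector(bv$values)), tolerance = 1e-9)
})

test_that("gradients through prost/project/inv_prost match finite differences", {
  # the operators are linear in the volume, so the gradient is exact
  n <- 6L
  g <- projection_geometry(detector_px = c(5, 5), pixel_mm = 2.5,
                           k_samples = 8, depth_window_mm = 14)
  ig <- inverse_grid(c(n, n, n), c(2, 2, 2), g)
  bidx <- prostreg:::world_to_index(
    matrix(beam_grid(g)$coords, 5 * 5 * 8, 3), c(n, n, n), c(2, 2, 2))
  lossfun <- function(v) {
    tp <- prostreg:::new_tape()
    vn <- prostreg:::tp_const(tp, array(v, c(n, n, n)))
    bv <- prostreg:::tp_sample(tp, vn, bidx)
    bv3 <- prostreg:::tp_reshape(tp, bv, c(5L, 5L, 8L))
    img <- prostreg:::tp_ray_sum(tp, bv3, 2)
    rec <- prostreg:::tp_sample(tp, bv3,
                                matrix(ig$coords, n^3, 3))
    L <- prostreg:::tp_node(tp, sum(prostreg:::tp_val(tp, img)^2) +
                              sum(prostreg:::tp_val(tp, rec)^2),
                            c(img, rec), function(gr) {
                              list(2 * gr * prostreg:::tp_val(tp, img),
                                   2 * gr * prostreg:::tp_val(tp, rec))
                            })
    gr <- prostreg:::tp_backward(tp, L)
    list(val = prostreg:::tp_val(tp, L), grad = gr[[vn]])
  }
  set.seed(6)
  v0 <- rnorm(n^3)
  r <- lossfun(v0)
  for (i in sample(n^3, 12)) {
    vp <- v0; vp[i] <- vp[i] + 1e-5
    vm <- v0; vm[i] <- vm[i] - 1e-5
    fd <- (lossfun(vp)$val - lossfun(vm)$val) / 2e-5
    expect_equal(as.vector(r$grad)[i], fd, tolerance = 1e-3)
  }
})

test_that("label projection yields the magnified disk and masks DRRs", {
  r <- 10
  W <- voxel_world_coords(c(40, 40, 40), c(1, 1, 1))
  lab <- array(as.numeric(sqrt(rowSums(W^2)) <= r), c(40, 40, 40))
  g <- projection_geometry(detector_px = c(65, 65), pixel_mm = 0.5,
                           k_samples = 64, depth_window_mm = 40)
  m <- project_labels(lab, g)
  expect_true(all(m %in% c(0, 1)))
  # disk radius ~ magnified ball radius (SDD/iso * r); the any-intersection
  # threshold plus trilinear support widens it by up to ~1 magnified half-voxel
  rad_px <- sqrt(sum(m) / pi)
  expect_lt(abs(rad_px * 0.5 - (1000 / 925) * r), 0.8)
  # empty labels -> empty mask
  expect_equal(sum(project_labels(lab * 0, g)), 0)
  # masking zeroes everything outside the projection of the labels
  p <- drr(prost_volume(lab), g)$pixels
  expect_true(all((p * (1 - m)) == 0))
})

test_that("images downsample, normalise and round-trip through files", {
  set.seed(8)
  img <- matrix(rnorm(64 * 48), 64, 48)
  dn <- downsample_image(img, c(32, 24))
  expect_equal(dim(dn), c(32L, 24L))
  expect_equal(dn[1, 1], mean(img[1:2, 1:2]))
  cst <- normalise01(matrix(5, 3, 3))
  expect_true(all(cst == 0))
  nrm <- normalise01(img)
  expect_equal(range(nrm), c(0, 1))

  f <- file.path(tempdir(), "p.nii.gz")
  write_projection(img, f)
  expect_equal(read_projection(f), img, tolerance = 1e-6, ignore_attr = TRUE)
  fp <- file.path(tempdir(), "p.png")
  write_projection(img, fp)
  r <- read_projection(fp)
  expect_equal(dim(r), dim(img))
  # PNG export is 8-bit quantised
  expect_lt(max(abs(r - normalise01(img))), 1 / 254)
})
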