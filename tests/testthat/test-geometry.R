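test_that("geometry transform realises the LAO/RAO and cranio-caudal rotations", {
  g0 <- projection_geometry()
  expect_equal(build_geometry_transform(g0), diag(4))

  # independent rotation matrix about the cranio-caudal (z) axis
  g90 <- projection_geometry(lao_rao_deg = 90)
  Rz90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  expect_equal(build_geometry_transform(g90)[1:3, 1:3], Rz90, tolerance = 1e-12)
  expect_equal(source_position(g90), as.vector(Rz90 %*% c(0, 925, 0)),
               tolerance = 1e-9)

  gp <- projection_geometry(lao_rao_deg = 30)
  gm <- projection_geometry(lao_rao_deg = -30)
  prod_rot <- build_geometry_transform(gp)[1:3, 1:3] %*%
    build_geometry_transform(gm)[1:3, 1:3]
  expect_equal(prod_rot, diag(3), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(source_position(gp), source_position(gm))))
})

test_that("source position sits at the isocentre distance for any angles", {
  expect_equal(source_position(projection_geometry()), c(0, 925, 0))
  g180 <- projection_geometry(lao_rao_deg = 180)
  expect_equal(source_position(g180), c(0, -925, 0), tolerance = 1e-9)
  set.seed(3)
  for (i in 1:5) {
    g <- projection_geometry(lao_rao_deg = runif(1, -180, 179),
                             cranio_caudal_deg = runif(1, -30, 30),
                             iso_mm = 700, sdd_mm = 1100)
    expect_equal(sqrt(sum(source_position(g)^2)), 700, tolerance = 1e-9)
  }
})

test_that("geometry constructor enforces its invariants", {
  expect_error(projection_geometry(iso_mm = 1100, sdd_mm = 1000), "invalid")
  expect_error(projection_geometry(lao_rao_deg = NaN), "invalid")
  expect_error(projection_geometry(detector_px = c(1, 64)), "invalid")
  expect_error(projection_geometry(k_samples = 1), "invalid")
  # theta stored in [-180, 180)
  expect_equal(projection_geometry(lao_rao_deg = 270)$lao_rao_deg, -90)
})

test_that("canonical grid rays are collinear with the source and uniform", {
  g <- projection_geometry(detector_px = c(33, 33), pixel_mm = 2,
                           k_samples = 41, depth_window_mm = 150,
                           lao_rao_deg = 25, cranio_caudal_deg = 5)
  bg <- beam_grid(g)
  s <- source_position(g)
  set.seed(1)
  for (rep in 1:6) {
    i <- sample(33, 1); j <- sample(33, 1)
    ray <- bg$coords[i, j, , ]
    dirs <- sweep(ray, 2, s)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    expect_lt(max(abs(sweep(dirs, 2, dirs[1, ]))), 1e-6)
    steps <- sqrt(rowSums(diff(ray)^2))
    expect_lt(diff(range(steps)), 1e-9)
    expect_equal(steps[1], bg$spacing_mm, tolerance = 1e-9)
  }
  # central pixel ray passes through the isocentre
  ctr <- bg$coords[17, 17, , ]
  expect_lt(min(sqrt(rowSums(ctr^2))), 1e-6)
})

test_that("an object at the isocentre is magnified by SDD/iso on the detector", {
  g <- projection_geometry(detector_px = c(65, 65), pixel_mm = 1,
                           k_samples = 32, depth_window_mm = 100)
  L <- 20
  ig_pt <- function(p) {
    # detector (i, j) of the ray through world point p (similar triangles)
    s <- source_position(g)
    d <- p - s
    q <- s + (g$sdd_mm / sum(d * -s / 925)) * d
    (q - c(0, 925 - 1000, 0))[c(1, 3)] / g$pixel_mm
  }
  u1 <- ig_pt(c(L / 2, 0, 0)); u2 <- ig_pt(c(-L / 2, 0, 0))
  proj_len <- sqrt(sum((u1 - u2)^2)) * g$pixel_mm[1]
  expect_equal(proj_len / L, 1000 / 925, tolerance = 1e-9)
})

test_that("inverse grid maps voxels to their beam coordinates", {
  g <- projection_geometry(detector_px = c(48, 48), pixel_mm = 1.5,
                           k_samples = 48, depth_window_mm = 80,
                           lao_rao_deg = 40)
  d <- c(33L, 33L, 33L)
  ig <- inverse_grid(d, c(1, 1, 1), g)
  # isocentre voxel -> central pixel, mid-window depth
  ctr <- (d + 1) %/% 2
  expect_equal(ig$coords[ctr[1], ctr[2], ctr[3], ],
               c((48 + 1) / 2, (48 + 1) / 2, (48 + 1) / 2), tolerance = 1e-6)
  expect_true(ig$mask[ctr[1], ctr[2], ctr[3]])

  # far out-of-cone voxels are masked invalid
  g_narrow <- projection_geometry(detector_px = c(8, 8), pixel_mm = 0.5,
                                  k_samples = 16, depth_window_mm = 10)
  ign <- inverse_grid(d, c(2, 2, 2), g_narrow)
  expect_false(all(ign$mask))
  expect_true(all(ign$coords[, , , 1][!ign$mask] == 0))
})

test_that("inverse grid round-trips beam grid points (forward ray-march oracle)", {
  g <- projection_geometry(detector_px = c(24, 28), pixel_mm = 2,
                           k_samples = 30, depth_window_mm = 90,
                           lao_rao_deg = -35, cranio_caudal_deg = 4)
  bg <- beam_grid(g)
  # brute-force oracle: walk the ray from the recovered (i, j) by the
  # recovered depth and compare with the original point
  s <- source_position(g)
  R <- build_geometry_transform(g)[1:3, 1:3]
  dc <- as.vector(R %*% c(0, 925 - 1000, 0))
  eu <- as.vector(R %*% c(1, 0, 0)); ev <- as.vector(R %*% c(0, 0, 1))
  a <- -s / 925
  set.seed(4)
  for (rep in 1:10) {
    ijk <- c(sample(24, 1), sample(28, 1), sample(30, 1))
    p <- bg$coords[ijk[1], ijk[2], ijk[3], ]
    dvec <- p - s; tlen <- sqrt(sum(dvec^2))
    q <- s + (g$sdd_mm / sum(dvec * a)) * dvec
    i <- sum((q - dc) * eu) / 2 + (24 + 1) / 2
    j <- sum((q - dc) * ev) / 2 + (28 + 1) / 2
    k <- (tlen - (925 - 45)) / (90 / 29) + 1
    expect_equal(c(i, j, k), ijk, tolerance = 1e-3)
  }
})

test_that("rotating the geometry equals rotating the volume the other way", {
  vol <- smooth_compact_volume(40, seed = 2)
  g0 <- geometry_for_volume(vol, detector_px = c(64, 64), k_samples = 64)
  g25 <- geometry_for_volume(vol, lao_rao_deg = 25, detector_px = c(64, 64),
                             k_samples = 64)
  p_rot_geom <- drr(vol, g25)
  vol_rot <- warp_affine(vol, affine_to_matrix(affine_params(rotation = c(0, 0, -25))))
  p_rot_vol <- drr(vol_rot, g0)
  expect_lt(max(abs(p_rot_geom$pixels - p_rot_vol$pixels)) / max(p_rot_geom$pixels),
            0.03)
})

test_that("geometry files round-trip through YAML and JSON", {
  g <- projection_geometry(lao_rao_deg = -12.5, cranio_caudal_deg = 3,
                           sdd_mm = 1000, iso_mm = 925,
                           detector_px = c(160, 224), pixel_mm = c(0.8, 0.9),
                           k_samples = 192, depth_window_mm = 246.2)
  for (ext in c("yaml", "json")) {
    f <- file.path(tempdir(), paste0("g.", ext))
    write_geometry(g, f)
    g2 <- read_geometry(f)
    expect_equal(unclass(g2), unclass(g), tolerance = 1e-12)
  }
})
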