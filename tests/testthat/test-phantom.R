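test_that("phantom generation is deterministic and respects its spec", {
  spec <- tiny_spec()
  v1 <- make_phantom(spec, seed = 3)
  v2 <- make_phantom(spec, seed = 3)
  expect_identical(v1$data, v2$data)
  expect_identical(v1$labels, v2$labels)
  v3 <- make_phantom(spec, seed = 4)
  expect_false(identical(v1$data, v3$data))

  # intensities ordered, label = support
  expect_true(all(v1$data[v1$labels == 0] <= spec$intensities[3] * 0.5 + 1e-9))
  expect_error(phantom_spec(intensities = c(1, 0.5, 0.2)), "ordered")
  expect_error(make_phantom(phantom_spec(shape = c(32, 32, 32),
                                         shaft_radius = 30), 0), "exceeds")
})

test_that("phantom label volume matches a fine Monte-Carlo estimate of the solid", {
  spec <- phantom_spec(shape = c(48, 48, 48), spacing = c(1, 1, 1))
  v <- make_phantom(spec, 0)
  pp <- attr(v, "params")
  vox_vol <- sum(v$labels) * prod(spec$spacing)
  set.seed(1)
  n_mc <- 4e5
  ext <- spec$shape * spec$spacing
  P <- cbind(runif(n_mc, -ext[1] / 2, ext[1] / 2),
             runif(n_mc, -ext[2] / 2, ext[2] / 2),
             runif(n_mc, -ext[3] / 2, ext[3] / 2))
  mc_vol <- mean(prostreg:::phantom_sdf(P, pp) > 0) * prod(ext)
  expect_lt(abs(vox_vol - mc_vol) / mc_vol, 0.05)
})

test_that("cortical shell voxels carry the cortical intensity, interior trabecular", {
  spec <- phantom_spec(shape = c(48, 48, 48), spacing = c(1, 1, 1))
  v <- make_phantom(spec, 0)
  pp <- attr(v, "params")
  d <- prostreg:::phantom_sdf(voxel_world_coords(spec$shape, spec$spacing), pp)
  aa <- 0.5 * min(spec$spacing)
  shell <- d > aa & d < spec$cortical_thickness - aa
  interior <- d > spec$cortical_thickness + aa
  expect_true(all(abs(v$data[shell] - spec$intensities[3]) < 1e-9))
  expect_true(all(abs(v$data[interior] - spec$intensities[2]) < 1e-9))
})

test_that("random poses stay inside their ranges and are seed-reproducible", {
  p0 <- random_pose(1, rot_deg = 0, trans_mm = 0, scale_frac = 0)
  expect_equal(affine_to_matrix(p0), diag(4))
  draws <- t(sapply(1:200, function(s) {
    p <- random_pose(s)
    c(p$rotation, p$translation, p$log_scale)
  }))
  expect_true(all(abs(draws[, 1:3]) <= 10))
  expect_true(all(abs(draws[, 4:6]) <= 4))
  expect_true(all(draws[, 7] >= log(0.95) & draws[, 7] <= log(1.05)))
  expect_identical(random_pose(42), random_pose(42))
  expect_false(identical(random_pose(42), random_pose(43)))
})

test_that("random deformations are smooth, bounded and diffeomorphic", {
  expect_true(all(random_deformation(1, amplitude = 0, grid_shape = c(8, 8, 8)) == 0))
  d <- c(24, 24, 24)
  for (seed in 1:5) {
    v <- random_deformation(seed, amplitude = 5, smoothness_sigma = 2.5,
                            grid_shape = d)
    nrm <- sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2)
    expect_equal(max(nrm), 5, tolerance = 1e-9)
    u <- integrate_velocity(v, 7)
    expect_true(all(jacobian_determinant(u) > 0))
    # flow of a bounded field stays within a modest factor of the amplitude
    unrm <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
    expect_lt(max(unrm), 5 * exp(1))
  }
})

test_that("case construction: identity case, masks, geometry modes, ground truth", {
  spec <- tiny_spec()
  id_case <- make_case(spec, 7, jitter_shape = FALSE, rot_deg = 0, trans_mm = 0,
                       scale_frac = 0, deform_amplitude_mm = 0)
  expect_equal(id_case$target$data, id_case$atlas$data, tolerance = 1e-12)

  case <- make_case(spec, 7)
  expect_true(all(dim(case$drr_ap) == case$input_px))
  expect_gt(sum(case$mask_ap), 0)
  expect_gt(sum(case$mask_lat), 0)
  expect_equal(case$geom_ap$lao_rao_deg, 0)
  expect_equal(case$geom_lat$lao_rao_deg, 90)
  expect_equal(range(case$drr_ap), c(0, 1))

  gen <- make_case(spec, 7, mode = "generalised")
  expect_true(abs(gen$geom_ap$lao_rao_deg) <= 30)
  expect_true(abs(gen$geom_lat$lao_rao_deg - 90) <= 30)

  # stored ground truth reproduces the target from the atlas instance
  instance <- make_phantom(spec, 7)
  rebuilt <- warp_dense(instance, case$truth$psi)
  expect_gt(ncc(rebuilt$data, case$target$data), 0.99)
})

test_that("unregistered phantom instances overlap moderately (population realism)", {
  # canonical pose: shape jitter + local deformation only, no pose component
  spec <- tiny_spec()
  atlas <- make_phantom(spec, 0)
  dvals <- sapply(1:6, function(s) {
    case <- make_case(spec, s, rot_deg = 0, trans_mm = 0, scale_frac = 0)
    dice(atlas$labels, case$target$labels)
  })
  expect_true(all(dvals > 0.5 & dvals < 0.98))
})

test_that("dataset writing: split arithmetic, determinism, file layout", {
  spec <- tiny_spec()
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- make_dataset(5, seed = 2, out_dir = d1, spec = spec)
  m2 <- make_dataset(5, seed = 2, out_dir = d2, spec = spec)
  expect_equal(lengths(m1$split), c(train = 3L, val = 1L, test = 1L))
  files <- c("atlas.nii.gz", "atlas_labels.nii.gz", "target.nii.gz",
             "target_labels.nii.gz", "drr_ap.nii.gz", "drr_lat.nii.gz",
             "geom_ap.yaml", "geom_lat.yaml", "truth.json", "psi_true.nii.gz")
  expect_true(all(file.exists(file.path(d1, "case_0001", files))))
  # identical content on re-generation with the same seed
  t1 <- jsonlite::read_json(file.path(d1, "case_0003", "truth.json"))
  t2 <- jsonlite::read_json(file.path(d2, "case_0003", "truth.json"))
  expect_identical(t1, t2)
  v1 <- read_volume(file.path(d1, "case_0002", "target.nii.gz"))
  v2 <- read_volume(file.path(d2, "case_0002", "target.nii.gz"))
  expect_equal(v1$data, v2$data, tolerance = 1e-7, ignore_attr = TRUE)
})
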