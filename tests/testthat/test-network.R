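test_that("configuration shape algebra follows the halving/doubling rules", {
  cfg <- reg_config("full")
  a <- cfg$affine
  feats <- a$base_features * 2^(seq_len(a$num_levels) - 1)
  expect_equal(feats, c(16, 32, 64, 128, 256))
  expect_equal(cfg$input_px / 2^a$num_levels, c(5, 7))

  lp <- prostreg:::local_plan(cfg)
  expect_equal(lp$n_enc, 5L)
  expect_equal(apply(lp$fac, 2, prod),
               c(f1 = 32, f2 = 32, f3 = cfg$k_samples / cfg$local$M))
  # decoder feature schedule as configured
  expect_equal(cfg$local$decoder_features, c(64, 32, 32, 16, 16, 16))

  expect_error(reg_config("tiny", input_px = c(20, 32)), "divisible")
})

test_that("M-fold stacking turns a 2D map into a ray-replicated 3D map", {
  tp <- prostreg:::new_tape()
  x <- array(rnorm(6 * 8 * 3), c(6, 8, 3))
  xn <- prostreg:::tp_const(tp, x)
  y <- prostreg:::tp_val(tp, prostreg:::tp_repeat_ray(tp, xn, 4))
  expect_equal(dim(y), c(6L, 8L, 4L, 3L))
  for (m in 1:4) expect_equal(y[, , m, ], x)
})

test_that("freshly initialised model is near the identity transform", {
  model <- init_registration_model(reg_config("tiny"), seed = 2)
  case <- tiny_case()
  r <- register_case(model, case)
  expect_lt(sqrt(sum(r$pose$rotation^2)), 0.5)
  expect_lt(sqrt(sum(r$pose$translation^2)), 0.5)
  expect_lt(abs(r$pose$log_scale), 0.01)
  expect_lt(mean(abs(r$phi)), 0.05)
})

test_that("untrained model output is structurally valid and self-consistent", {
  model <- init_registration_model(reg_config("tiny"), seed = 3)
  case <- tiny_case()
  r <- register_case(model, case)
  vd <- model$config$volume_dim
  expect_equal(dim(r$phi), c(vd, 3L))
  expect_equal(dim(r$psi), c(vd, 3L))
  expect_equal(dim(r$warped_volume$data), vd)
  expect_true(all(is.finite(r$phi)) && all(is.finite(r$psi)))
  expect_true(all(r$warped_labels %in% c(0, 1)))
  # psi is definitionally the composition of T and phi
  expect_equal(r$psi, compose_affine_local(affine_to_matrix(r$pose), r$phi,
                                           model$config$spacing))
})

test_that("zero fusion weights give zero velocity, hence an identity local field", {
  model <- init_registration_model(reg_config("tiny"), seed = 4)
  model$params$fusion_W[] <- 0
  model$params$fusion_b[] <- 0
  r <- register_case(model, tiny_case())
  expect_true(all(r$velocity == 0))
  expect_true(all(r$phi == 0))
})

test_that("inference is deterministic and idempotent, artefacts written once", {
  model <- init_registration_model(reg_config("tiny"), seed = 5)
  case <- tiny_case()
  r1 <- register_case(model, case)
  r2 <- register_case(model, case)
  expect_identical(r1$psi, r2$psi)
  out <- file.path(tempdir(), "regout")
  unlink(out, recursive = TRUE)
  register_case(model, case, out_dir = out)
  expect_setequal(list.files(out),
                  c("warped_volume.nii.gz", "warped_labels.nii.gz",
                    "phi.nii.gz", "psi.nii.gz", "pose.json"))
  lab <- read_volume(file.path(out, "warped_labels.nii.gz"))
  expect_true(all(lab$data %in% c(0, 1)))
})

test_that("all ablation variants build and run forward", {
  case <- tiny_case()
  variants <- list(
    list(intermediate = FALSE, skip = TRUE, dual = TRUE, invp = TRUE),
    list(intermediate = TRUE, skip = FALSE, dual = TRUE, invp = TRUE),
    list(intermediate = TRUE, skip = TRUE, dual = FALSE, invp = TRUE),
    list(intermediate = TRUE, skip = TRUE, dual = TRUE, invp = FALSE))
  for (vn in variants) {
    cfg <- reg_config("tiny",
                      affine = list(intermediate_concat = vn$intermediate),
                      local = list(skip_connections = vn$skip,
                                   dual_decoders = vn$dual,
                                   use_inv_prost = vn$invp))
    model <- init_registration_model(cfg, seed = 6)
    r <- register_case(model, case)
    expect_equal(dim(r$phi), c(cfg$volume_dim, 3L))
    expect_true(all(is.finite(r$phi)))
  }
})

test_that("loss attains -2 exactly for a perfect double match with zero field", {
  spec <- tiny_spec()
  case <- make_case(spec, 6)
  perfect <- list(warped_affine = case$target, warped_volume = case$target,
                  phi = array(0, c(spec$shape, 3)))
  expect_equal(registration_loss(perfect, case), -2)
  # delta = 0 removes the smoothness term exactly
  imperfect <- perfect
  imperfect$phi <- random_deformation(2, 3, 3, spec$shape)
  expect_equal(registration_loss(imperfect, case, delta = 0), -2)
  expect_gt(registration_loss(imperfect, case, delta = 0.01), -2)
  # lower bound
  off <- list(warped_affine = case$atlas, warped_volume = case$atlas,
              phi = imperfect$phi)
  expect_gte(registration_loss(off, case), -2)
})

test_that("NCC is a normalised correlation with affine-intensity invariance", {
  v <- make_phantom(tiny_spec(), 0)$data
  expect_equal(ncc(v, v), 1)
  expect_equal(ncc(v, -v), -1)
  expect_equal(ncc(v, 2.5 * v + 1), 1, tolerance = 1e-12)
  expect_warning(z <- ncc(v, v * 0), "zero-variance")
  expect_equal(z, 0)
})

test_that("smoothness penalty: zero for rigid shifts, closed form for scalings", {
  d <- c(12, 12, 12)
  expect_equal(smoothness(array(0, c(d, 3))), 0)
  cfield <- array(0, c(d, 3)); cfield[, , , 2] <- 4.2
  expect_equal(smoothness(cfield), 0)
  # u(x) = (s-1) x: each forward difference along axis a of channel a is (s-1)
  s <- 1.3
  W <- voxel_world_coords(d, c(1, 1, 1))
  us <- array((s - 1) * W, c(d, 3))
  expected <- 3 * (s - 1)^2 * (d[1] - 1) * d[2] * d[3] / prod(d)
  expect_equal(smoothness(us), expected, tolerance = 1e-12)
})

test_that("training is seed-deterministic and logs a history", {
  spec <- tiny_spec()
  cases <- lapply(1:3, function(i) make_case(spec, i, deform_amplitude_mm = 2))
  cfg <- reg_config("tiny")
  m1 <- init_registration_model(cfg, seed = 11)
  m2 <- init_registration_model(cfg, seed = 11)
  expect_identical(m1$params, m2$params)
  t1 <- train_registration(m1, cases[1:2], val_cases = cases[3], epochs = 1,
                           affine_only = TRUE, seed = 5, verbose = FALSE)
  t2 <- train_registration(m2, cases[1:2], val_cases = cases[3], epochs = 1,
                           affine_only = TRUE, seed = 5, verbose = FALSE)
  expect_identical(t1$history, t2$history)
  expect_equal(names(t1$history), c("epoch", "train_loss", "val_dice"))
  expect_error(train_registration(m1, list()), "empty")
})

test_that("models save and load through the checkpoint sidecar", {
  model <- init_registration_model(reg_config("tiny"), seed = 8)
  base <- file.path(tempdir(), "ckpt")
  save_model(model, base)
  m2 <- load_model(base)
  expect_identical(m2$params, model$params)
  expect_equal(unclass(m2$config)[c("volume_dim", "input_px", "k_samples")],
               unclass(model$config)[c("volume_dim", "input_px", "k_samples")])
  r1 <- register_case(model, tiny_case())
  r2 <- register_case(m2, tiny_case())
  expect_equal(r1$psi, r2$psi)
})
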