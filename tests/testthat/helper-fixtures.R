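# Shared fixtures, built in code at test time.

# smooth random phantom with compact support inside a ball of radius r_supp
smooth_compact_volume <- function(n = 48, seed = 1, sigma = 4, r_supp = 0.38 * n) {
  set.seed(seed)
  v <- array(rnorm(n^3), c(n, n, n))
  v <- prostreg:::gaussian_smooth3d(v, sigma)
  v <- (v - min(v)) / (max(v) - min(v))
  W <- voxel_world_coords(c(n, n, n), c(1, 1, 1))
  supp <- pmin(pmax((r_supp - sqrt(rowSums(W^2))) / 3, 0), 1)
  prost_volume(v * array(supp, c(n, n, n)), c(1, 1, 1))
}

# anti-aliased unit ball of radius r (mm) on an n^3 unit-spacing grid
ball_volume <- function(n = 64, r = 24) {
  W <- voxel_world_coords(c(n, n, n), c(1, 1, 1))
  d <- sqrt(rowSums(W^2))
  prost_volume(array(pmin(pmax(r - d + 0.5, 0), 1), c(n, n, n)), c(1, 1, 1))
}

# analytic chord length of the ray through each detector pixel across a
# centred ball of radius r (brute-force similar-triangles oracle)
ball_chord_map <- function(geom, r) {
  bg <- beam_grid(geom)
  s <- source_position(geom)
  P0 <- matrix(bg$coords[, , 1, ], prod(geom$detector_px), 3)
  D <- sweep(P0, 2, s)
  D <- D / sqrt(rowSums(D^2))
  Sm <- matrix(s, nrow(D), 3, byrow = TRUE)
  closest <- Sm - D * rowSums(Sm * D)
  dd <- sqrt(rowSums(closest^2))
  chord <- numeric(length(dd))
  inside <- dd < r
  chord[inside] <- 2 * sqrt(r^2 - dd[inside]^2)
  list(chord = matrix(chord, geom$detector_px[1], geom$detector_px[2]),
       dist = matrix(dd, geom$detector_px[1], geom$detector_px[2]))
}

tiny_spec <- function() phantom_spec(shape = c(32, 32, 32), spacing = c(1, 1, 1))

# cheap pure-pose case cache for network tests
tiny_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_case(tiny_spec(), 5)
    cache
  }
})
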