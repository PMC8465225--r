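min_pair_dist <- function(config) min(stats::dist(config$coords))

test_that("rg_of is the RMS distance from the centroid", {
  expect_equal(rg_of(matrix(c(5, -2, 7), nrow = 1)), 0)
  expect_equal(rg_of(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  # four corners of a unit square
  sq <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1), 0)
  expect_equal(rg_of(sq), sqrt(0.5))
  expect_error(rg_of(matrix(numeric(0), ncol = 3)), "at least one")
})

test_that("rg_of is invariant under translation of the frame", {
  set.seed(42)
  for (i in 1:10) {
    coords <- matrix(rnorm(3 * 25), ncol = 3)
    shift <- matrix(rnorm(3), nrow = 25, ncol = 3, byrow = TRUE)
    expect_equal(rg_of(coords + shift), rg_of(coords), tolerance = 1e-12)
  }
})

test_that("straight rope: coordinates and closed form are the same Rg", {
  for (N in c(1, 2, 5, 20, 40, 60)) {
    sr <- straight_rope(N)
    expect_equal(rg_of(sr), sqrt((N^2 - 1) / 3), tolerance = 1e-12)
    expect_equal(sr$rg, rg_of(sr), tolerance = 1e-12)
  }
  expect_equal(straight_rope(2)$rg, 1)
  expect_equal(straight_rope(20)$rg, 11.53, tolerance = 0.005)
  expect_equal(straight_rope(40)$rg, 23.08, tolerance = 0.005)
  expect_gte(min_pair_dist(straight_rope(30)), 2)
})

test_that("ring: all centers at radius N/(2*pi), Rg exactly R", {
  for (N in c(3, 20, 50)) {
    rn <- ring(N)
    expect_equal(rg_of(rn), N / (2 * pi), tolerance = 1e-12)
    radii <- sqrt(rowSums(rn$coords^2))
    expect_equal(radii, rep(N / (2 * pi), N), tolerance = 1e-12)
  }
  expect_equal(ring(50)$rg, 8.0, tolerance = 0.05)
  expect_equal(ring(20)$rg, 3.2, tolerance = 0.05)
  expect_error(ring(2), "at least 3")
  # the ring monomers are unit-diameter; neighbors sit on a chord, within
  # 1% of touching for N >= 10
  expect_equal(ring(20)$r_mono, 0.5)
  expect_gte(min_pair_dist(ring(20)), 2 * ring(20)$r_mono * 0.99)
  # perimeter convention doubles the radius
  expect_equal(ring(20, convention = "perimeter")$rg, 20 / pi)
  expect_equal(ring(20, convention = "perimeter")$r_mono, 1)
})

test_that("dense-sphere shell capacities follow the volume bound", {
  expect_equal(shell_capacity(1:5), c(1, 7, 19, 37, 61))
  expect_true(all(diff(shell_capacity(1:10)) > 0))
  k <- 1:10
  cum <- cumsum(shell_capacity(k))
  expect_equal(cum, k^3)                 # cumulative count = k^3 exactly
  expect_true(all(cum <= (2 * k - 1)^3)) # within the R^3/r^3 volume bound
  expect_error(shell_capacity(0), ">= 1")
})

test_that("dense sphere reproduces the shell-accounting Rg", {
  expect_equal(dense_sphere_rg(1), 0)
  expect_equal(dense_sphere_rg(20), 3.3, tolerance = 0.05)
  expect_equal(dense_sphere_rg(40), 4.5, tolerance = 0.05)
  # explicit accounting at N = 40: 1 + 7 + 19 placed, 13 at radius 6
  expect_equal(dense_sphere_rg(40),
               sqrt((7 * 4 + 19 * 16 + 13 * 36) / 40), tolerance = 1e-12)
  ds <- dense_sphere(40)
  expect_equal(ds$N, 40)
  # every placed monomer sits exactly on its shell radius
  radii <- sort(unique(round(sqrt(rowSums(ds$coords^2)), 9)))
  expect_equal(radii, c(0, 2, 4, 6))
  # coordinate Rg differs from the shell form only by the centroid offset
  expect_equal(rg_of(ds), ds$rg, tolerance = 0.05)
})

test_that("dense-sphere placements never overlap", {
  for (N in c(2, 8, 20, 27, 40, 64, 100, 200)) {
    expect_gte(min_pair_dist(dense_sphere(N)), 2 - 1e-9)
  }
})

test_that("sparse sphere is the (N^(1/3)+1)/N^(1/3) dilation of the dense sphere", {
  expect_equal(sparse_sphere_rg(1), 0)
  for (N in c(5, 20, 40, 60)) {
    scale <- (N^(1 / 3) + 1) / N^(1 / 3)
    expect_equal(sparse_sphere_rg(N), dense_sphere_rg(N) * scale,
                 tolerance = 1e-12)
    expect_gt(sparse_sphere_rg(N), dense_sphere_rg(N))
  }
  expect_equal(sparse_sphere_rg(20), 4.7, tolerance = 0.3)
  expect_equal(sparse_sphere(40)$rg, sparse_sphere_rg(40), tolerance = 1e-12)
})

test_that("parabola places symmetric equal-arc steps on y = x^2", {
  # two monomers: Rg is half the center separation
  pa2 <- parabola(2)
  expect_equal(pa2$rg, abs(pa2$coords[2, 1]), tolerance = 1e-9)
  for (N in c(7, 20)) {
    pa <- parabola(N)
    expect_equal(nrow(pa$coords), N)
    # mirror symmetry about the parabola axis
    expect_equal(mean(pa$coords[, 1]), 0, tolerance = 1e-9)
    expect_equal(pa$coords[, 2], pa$coords[, 1]^2, tolerance = 1e-9)
    # consecutive centers are one arc step apart: chord <= step, close to it
    chords <- sqrt(rowSums(diff(pa$coords)^2))
    expect_true(all(chords <= 1 + 1e-9))
    expect_true(all(chords > 0.85))
    # odd N puts one monomer at the apex
    if (N %% 2 == 1) expect_true(any(rowSums(abs(pa$coords)) == 0))
  }
  # nominal Rg and direct evaluation of the coordinates agree (same path
  # by construction, checked against an independent recomputation)
  pa20 <- parabola(20)
  centered <- sweep(pa20$coords, 2, colMeans(pa20$coords))
  expect_equal(pa20$rg, sqrt(sum(centered^2) / 20), tolerance = 1e-12)
  # diameter-2 stepping is available for unit-radius monomers
  expect_gt(parabola(20, step = 2)$rg, pa20$rg)
  expect_error(parabola(1), "at least 2")
})

test_that("self-avoiding walks are reproducible, touching and non-overlapping", {
  expect_equal(saw_walk(1, seed = 1)$rg, 0)
  w1 <- saw_walk(60, seed = 99)
  w2 <- saw_walk(60, seed = 99)
  expect_identical(w1$coords, w2$coords)   # determinism contract
  bonds <- sqrt(rowSums(diff(w1$coords)^2))
  expect_equal(bonds, rep(2, 59), tolerance = 1e-12)  # touching beads
  expect_gte(min_pair_dist(w1), 2 - 1e-6)             # hard-sphere exclusion
  w3 <- saw_walk(60, seed = 100)
  expect_false(identical(w1$coords, w3$coords))
})

test_that("small SAW ensembles scale with the self-avoiding exponent", {
  set.seed(2024)
  Ns <- c(10, 20, 40)
  mean_rg <- vapply(Ns, function(N) {
    mean(vapply(1:200, function(i) saw_walk(N)$rg, numeric(1)))
  }, numeric(1))
  nu_hat <- fit_scaling(Ns, mean_rg)$nu_hat
  expect_gt(nu_hat, 0.5)
  expect_lt(nu_hat, 0.7)
})

test_that("configuration sizes are ordered as the idealized shapes predict", {
  for (N in c(20, 30, 40, 50)) {
    expect_lt(dense_sphere_rg(N), parabola(N)$rg)
    expect_lt(parabola(N)$rg, straight_rope(N)$rg)
    expect_lt(sparse_sphere_rg(N), straight_rope(N)$rg)
  }
  # the full DS < Pa < SS < SR chain holds for the smaller chains; at
  # N >= 40 the parabola construction outgrows the sparse sphere
  for (N in c(20, 30)) {
    expect_lt(parabola(N)$rg, sparse_sphere_rg(N))
  }
})

test_that("XYZ export writes the standard layout", {
  path <- tempfile(fileext = ".xyz")
  cfg <- dense_sphere(27)
  write_xyz(cfg, path)
  lines <- readLines(path)
  expect_equal(lines[1], "27")
  expect_match(lines[2], "shape=DS N=27")
  expect_length(lines, 29)
  fields <- strsplit(lines[3], " ")[[1]]
  expect_equal(fields[1], "C")
  coords <- do.call(rbind, lapply(lines[-(1:2)], function(l) {
    as.numeric(strsplit(l, " ")[[1]][-1])
  }))
  expect_equal(rg_of(coords), rg_of(cfg), tolerance = 1e-5)
})
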