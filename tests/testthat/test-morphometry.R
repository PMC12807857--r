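# 3D morphometry: mesh surface area, shape descriptors and their exact
# algebraic relationships, feature standardization, embedding and KDE.

test_that("digitized sphere surface area is within 5% of 4*pi*r^2", {
  lm <- as_label_map(sphere_mask(10))
  sa <- surface_area(lm, 1)
  expect_lt(abs(sa - 4 * pi * 100) / (4 * pi * 100), 0.05)
  expect_error(surface_area(lm, 7), "not found")
})

test_that("surface area handles degenerate voxels and is translation-invariant", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  sa1 <- surface_area(as_label_map(m), 1)
  expect_gt(sa1, 0)
  expect_true(is.finite(sa1))
  a <- surface_area(as_label_map(sphere_mask(6)), 1)
  b <- surface_area(as_label_map(sphere_mask(6, center_offset = c(1, 2, 1))), 1)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("sphere descriptors hit their closed forms up to discretization", {
  lm <- as_label_map(sphere_mask(10))
  f <- compute_features(lm, uniform_grid(c(dim(lm$labels), 1), 2.5))
  expect_gte(f$sphericity, 0.9)
  expect_lte(f$sphericity, 1.0)
  expect_gte(f$complexity, 1.0)
  expect_lte(f$complexity, 1.2)
  expect_gt(f$roundness, 0.95)
  expect_gt(f$compactness, 0.95)
  expect_equal(f$mean_intensity_ch1, 2.5)
  expect_equal(f$integrated_density_ch1, 2.5 * f$voxel_count)
  expect_equal(f$volume_um3, f$voxel_count * 1)
})

test_that("a long capsule is less spherical and more complex than a sphere", {
  r <- 4
  caps <- as_label_map(capsule_mask(r, 10 * r))
  sph <- as_label_map(sphere_mask(r))
  fc <- compute_features(caps, uniform_grid(c(dim(caps$labels), 1)))
  fs <- compute_features(sph, uniform_grid(c(dim(sph$labels), 1)))
  expect_lt(fc$sphericity, fs$sphericity)
  expect_lt(fc$roundness, fs$roundness)
  expect_gt(fc$complexity, fs$complexity)
  # closed-form capsule: SA = 2*pi*r*L + 4*pi*r^2, V = pi*r^2*L + 4/3*pi*r^3
  L <- 10 * r
  sa_true <- 2 * pi * r * L + 4 * pi * r^2
  v_true <- pi * r^2 * L + 4 / 3 * pi * r^3
  expect_lt(abs(fc$surface_area_um2 - sa_true) / sa_true, 0.06)
  expect_lt(abs(fc$volume_um3 - v_true) / v_true, 0.05)
})

test_that("complexity times sphericity cubed is exactly 1 on every record", {
  sc <- make_cell_volume(small_scene(seed = 12, n = 5))
  seg <- segment_stack(sc$grid, segmentation_config(min_voxels = 200))
  f <- compute_features(seg$label_map, seg$grid_iso)
  expect_gt(nrow(f), 0)
  expect_equal(f$complexity * f$sphericity^3, rep(1, nrow(f)),
               tolerance = 1e-12)
})

test_that("sphericity and complexity are invariant to spacing rescaling", {
  m <- capsule_mask(3, 12)
  f1 <- compute_features(as_label_map(m, spacing = c(1, 1, 1)),
                         uniform_grid(c(dim(m), 1), spacing = c(1, 1, 1)))
  s <- 0.31
  f2 <- compute_features(as_label_map(m, spacing = rep(s, 3)),
                         uniform_grid(c(dim(m), 1), spacing = rep(s, 3)))
  expect_equal(f2$sphericity, f1$sphericity, tolerance = 1e-9)
  expect_equal(f2$complexity, f1$complexity, tolerance = 1e-9)
  expect_equal(f2$volume_um3, f1$volume_um3 * s^3, tolerance = 1e-9)
  expect_equal(f2$surface_area_um2, f1$surface_area_um2 * s^2,
               tolerance = 1e-9)
})

test_that("feature extraction is permutation-invariant over label ids", {
  m <- array(0L, c(8, 8, 20))
  m[3:6, 3:6, 3:6] <- 1L
  m[2:7, 2:7, 12:17] <- 2L
  g <- uniform_grid(c(8, 8, 20, 1))
  f12 <- compute_features(label_map(m, c(1, 1, 1)), g)
  m2 <- m
  m2[m == 1L] <- 2L; m2[m == 2L] <- 1L
  f21 <- compute_features(label_map(m2, c(1, 1, 1)), g)
  cols <- c("voxel_count", "volume_um3", "surface_area_um2", "sphericity")
  expect_equal(f12[f12$organelle_id == 1, cols],
               f21[f21$organelle_id == 2, cols], ignore_attr = TRUE)
})

test_that("solidity separates convex from concave shapes", {
  # C-shape: a box with a notch removed is far from convex
  box <- array(FALSE, c(10, 12, 12))
  box[3:8, 3:10, 3:10] <- TRUE
  cshape <- box
  cshape[3:8, 5:8, 5:10] <- FALSE
  expect_gt(mitoinherit:::voxel_solidity(box), 0.98)
  expect_lt(mitoinherit:::voxel_solidity(cshape), 0.8)
})

test_that("convex hull volume matches a brute-force facet oracle", {
  set.seed(7)
  for (i in 1:3) {
    pts <- matrix(rnorm(3 * 12), ncol = 3)
    expect_equal(mitoinherit:::.cpp_convex_hull_volume(pts),
                 hull_volume_oracle(pts), tolerance = 1e-8)
  }
  cube <- as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2)))
  expect_equal(mitoinherit:::.cpp_convex_hull_volume(cube), 8, tolerance = 1e-9)
})

test_that("standardization yields z-scores and a reusable scaling", {
  sc <- make_cell_volume(small_scene(seed = 22, n = 5))
  seg <- segment_stack(sc$grid, segmentation_config(min_voxels = 200))
  f <- compute_features(seg$label_map, seg$grid_iso)
  m <- standardize_features(f)
  expect_true(all(abs(colMeans(m)) < 1e-10))
  expect_true(all(abs(apply(m, 2, sd) - 1) < 1e-10))
  # round trip on held-out rows reproduces the train-time transform
  again <- apply_scaling(m, f)
  expect_equal(unname(again), unname(m[, colnames(again)]), tolerance = 1e-12)
  # duplicated rows standardize identically
  f2 <- rbind(f, f[1, ])
  m2 <- standardize_features(f2)
  expect_equal(unname(m2[1, ]), unname(m2[nrow(m2), ]))
  # zero-variance column dropped with a message
  f$constant <- 5
  expect_message(
    m3 <- standardize_features(f, c("volume_um3", "constant")),
    "zero-variance")
  expect_equal(colnames(m3), "volume_um3")
  f$allsame <- 1
  expect_error(standardize_features(f, "allsame"), "zero variance")
})

test_that("embedding is deterministic and separates distinct shape families", {
  set.seed(5)
  fam1 <- matrix(rnorm(40 * 3, mean = 0), ncol = 3)
  fam2 <- matrix(rnorm(40 * 3, mean = 6), ncol = 3)
  m <- rbind(fam1, fam2)
  colnames(m) <- c("a", "b", "c")
  e1 <- embed_features(m, seed = 1)
  e2 <- embed_features(m, seed = 1)
  expect_identical(e1, e2)
  lab <- rep(1:2, each = 40)
  # silhouette of the true families in embedded space is positive
  d <- as.matrix(dist(e1))
  sil <- vapply(seq_len(nrow(e1)), function(i) {
    a <- mean(d[i, lab == lab[i] & seq_along(lab) != i])
    b <- mean(d[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0)
  # duplicated point cloud: finite coordinates, no crash
  dup <- m[rep(1, 10), ]
  expect_warning(e3 <- embed_features(dup[1:2, ], seed = 1), "fewer than 3")
  e4 <- embed_features(dup, seed = 1)
  expect_true(all(is.finite(e4)))
})

test_that("the KDE integrates to 1 and places modes correctly", {
  set.seed(9)
  tight <- cbind(rnorm(200, 0, 0.05), rnorm(200, 0, 0.05))
  k <- kde_density(tight, bandwidth = 0.1, n_grid = 96)
  cell <- diff(k$x[1:2]) * diff(k$y[1:2])
  expect_lt(abs(sum(k$z) * cell - 1), 0.01)
  mode_idx <- which(k$z == max(k$z), arr.ind = TRUE)
  expect_lt(abs(k$x[mode_idx[1]] - mean(tight[, 1])), diff(k$x[1:2]) * 2)
  expect_lt(abs(k$y[mode_idx[2]] - mean(tight[, 2])), diff(k$y[1:2]) * 2)
  # two equal clusters give two modes of equal height within 5%
  two <- rbind(cbind(rnorm(400, -3, 0.1), rnorm(400, 0, 0.1)),
               cbind(rnorm(400, 3, 0.1), rnorm(400, 0, 0.1)))
  k2 <- kde_density(two, bandwidth = 0.2, n_grid = 128)
  left <- max(k2$z[k2$x < 0, ])
  right <- max(k2$z[k2$x > 0, ])
  expect_lt(abs(left - right) / max(left, right), 0.05)
  expect_error(kde_density(tight, bandwidth = -1), "positive")
  # independent cross-check against the classical reference implementation
  if (requireNamespace("MASS", quietly = TRUE)) {
    kd <- MASS::kde2d(tight[, 1], tight[, 2], h = 0.1 * 4,
                      n = 96, lims = c(range(k$x), range(k$y)))
    expect_equal(k$z, kd$z, tolerance = 1e-8)
  }
})
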