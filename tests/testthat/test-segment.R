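# Segmentation stack: resampling, fusion, outline enhancement, multi-Otsu,
# morphological cleanup, labelling and the size filter.

test_that("isotropic resampling preserves constants, extent and mass", {
  cc <- voxel_grid(array(3.3, c(5, 10, 10)), c(0.3, 0.1, 0.1))
  ci <- resample_isotropic(cc)
  expect_equal(unname(ci$spacing_um), rep(0.1, 3))
  expect_equal(range(ci$data), c(3.3, 3.3))
  # physical extent preserved within one voxel per axis
  expect_lt(abs(dim(ci$data)[1] * 0.1 - 5 * 0.3), 0.3 + 1e-9)

  # smooth blob: total intensity preserved within 2%
  sc <- make_cell_volume(small_scene(seed = 5, n = 3, noise = FALSE))
  gi <- resample_isotropic(sc$grid)
  m0 <- sum(sc$grid$data[, , , 1]) * prod(sc$grid$spacing_um)
  m1 <- sum(gi$data[, , , 1]) * prod(gi$spacing_um)
  expect_lt(abs(m1 - m0) / m0, 0.02)

  # paper-like anisotropy: z extent preserved within one z-step
  g <- voxel_grid(array(runif(20 * 12 * 12), c(20, 12, 12)),
                  c(0.13, 0.043, 0.043))
  gi2 <- resample_isotropic(g, 0.043)
  expect_equal(unname(gi2$spacing_um), rep(0.043, 3))
  expect_lt(abs(dim(gi2$data)[1] * 0.043 - 20 * 0.13), 0.13 + 1e-9)
  expect_error(resample_isotropic(g, -1), "positive")
  expect_error(resample_isotropic(g, 0.2), "finest")
})

test_that("channel fusion is a max of min-max normalized channels", {
  a <- array(0, c(4, 6, 6)); a[2, 2, 2] <- 8
  b <- array(0, c(4, 6, 6)); b[3, 4, 4] <- 2
  g <- voxel_grid(array(c(a, b), c(4, 6, 6, 2)), c(1, 1, 1),
                  channel_names = c("Tom20", "SnapTag"))
  one <- fuse_channels(g, "Tom20")
  expect_equal(max(one), 1)
  expect_equal(one[2, 2, 2], 1)
  both_same <- voxel_grid(array(c(a, a), c(4, 6, 6, 2)), c(1, 1, 1))
  expect_equal(fuse_channels(both_same), fuse_channels(both_same, "ch1"))
  # disjoint-support channels: fused support is the union
  fused <- fuse_channels(g)
  expect_equal(sum(fused > 0), 2)
  expect_equal(fused[3, 4, 4], 1)  # present only in the age channel
  expect_error(fuse_channels(g, "missing"), "unknown channel")
})

test_that("outline enhancement is identity at alpha 0 and peaks on edges", {
  v <- array(runif(4 * 5 * 6), c(4, 5, 6))
  expect_identical(enhance_outlines(v, 0.1, 0, c(1, 1, 1)), v)
  const <- array(0.5, c(6, 6, 6))
  out <- enhance_outlines(const, 0.5, 0.5, c(1, 1, 1))
  expect_equal(diff(range(out)), 0)
  # step edge along x: the added gradient term is maximal on the edge plane
  step <- array(rep(c(0, 0, 0, 0, 1, 1, 1, 1), each = 64), c(8, 8, 8))
  enh <- enhance_outlines(step, 1, 1, c(1, 1, 1))
  prof <- apply(enh - min(enh), 3, max)
  expect_true(which.max(prof) %in% c(4, 5))
  expect_error(enhance_outlines(v, -0.2, 0.5, c(1, 1, 1)), "nonnegative")
})

test_that("multi-Otsu matches the exhaustive between-class-variance oracle", {
  set.seed(42)
  v3 <- c(rnorm(800, 10, 1), rnorm(800, 30, 1.5), rnorm(400, 60, 2))
  expect_equal(multi_otsu_thresholds(v3, 3, 64), otsu_oracle(v3, 3, 64))
  th <- multi_otsu_thresholds(v3, 3, 64)
  expect_true(th[1] > 10 && th[1] < 30 && th[2] > 30 && th[2] < 60)
  # k = 2 reproduces classical Otsu on several draws
  for (s in 1:3) {
    set.seed(s)
    v2 <- c(rnorm(500, 5, 1), rnorm(300, 20, 2))
    expect_equal(multi_otsu_thresholds(v2, 2, 64), otsu_oracle(v2, 2, 64))
  }
  vb <- rep(c(0, 10), each = 1000)
  t1 <- multi_otsu_thresholds(vb, 2)
  expect_true(t1 > 0 && t1 < 10)
  expect_error(multi_otsu_thresholds(rep(1, 10), 2), "distinct")
})

test_that("binarize_and_clean fills holes and splits kissing spheres", {
  # solid sphere with one interior hole voxel
  m <- sphere_mask(5)
  c0 <- (dim(m)[1] + 1) / 2
  holey <- m * 1
  holey[c0, c0, c0] <- 0
  cfg <- segmentation_config(morph_ops = c("fill"))
  cleaned <- binarize_and_clean(holey, 0.5, cfg)
  expect_true(cleaned[c0, c0, c0])
  expect_equal(sum(cleaned), sum(m))

  # two spheres touching at one voxel separate after erosion
  r <- 4; n <- 4 * r + 7
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  c1 <- c((n + 1) / 2, (n + 1) / 2, (n + 1) / 2 - r)
  c2 <- c((n + 1) / 2, (n + 1) / 2, (n + 1) / 2 + r)
  kiss <- array((g$z - c1[1])^2 + (g$y - c1[2])^2 + (g$x - c1[3])^2 <= r^2 |
                  (g$z - c2[1])^2 + (g$y - c2[2])^2 + (g$x - c2[3])^2 <= r^2,
                c(n, n, n))
  before <- label_components(kiss, c(1, 1, 1), 6L)
  expect_equal(length(label_ids(before)), 1)
  er <- binarize_and_clean(kiss * 1, 0.5,
                           segmentation_config(morph_ops = "erosion"))
  after <- label_components(er, c(1, 1, 1), 6L)
  expect_equal(length(label_ids(after)), 2)

  expect_warning(
    empty <- binarize_and_clean(array(0, c(4, 4, 4)), 0.5,
                                segmentation_config(morph_ops = "erosion")),
    "empty")
  expect_false(any(empty))
})

test_that("connected-component labelling honours connectivity", {
  expect_equal(length(label_ids(label_components(array(FALSE, c(3, 3, 3)),
                                                 c(1, 1, 1)))), 0)
  m <- array(FALSE, c(9, 9, 20))
  m[3:5, 3:5, 3:5] <- TRUE
  m[3:5, 3:5, 12:14] <- TRUE
  expect_equal(length(label_ids(label_components(m, c(1, 1, 1)))), 2)
  # diagonal chain: one component at 26-connectivity, three at 6
  d <- array(FALSE, c(3, 3, 3))
  d[1, 1, 1] <- TRUE; d[2, 2, 2] <- TRUE; d[3, 3, 3] <- TRUE
  expect_equal(length(label_ids(label_components(d, c(1, 1, 1), 26L))), 1)
  expect_equal(length(label_ids(label_components(d, c(1, 1, 1), 6L))), 3)
})

test_that("the size filter removes strictly-smaller components only", {
  m <- array(0L, c(10, 30, 60))
  m[1:5, 1:10, 1:10] <- 1L                       # 500 voxels exactly
  m[1:5, 1:10, 21:30] <- 2L; m[1, 1, 30] <- 0L   # 499 voxels
  m[1:2, 1:5, 41:50] <- 3L                       # 100 voxels
  lm <- label_map(m, c(1, 1, 1))
  kept <- filter_small(lm, 500)
  expect_equal(sort(unique(as.integer(kept$labels))), c(0L, 1L))
  expect_equal(sum(kept$labels == 1L), 500)
  # min_voxels = 1 is the identity
  expect_equal(filter_small(lm, 1)$labels, lm$labels)
  # both planted sub-threshold components are gone
  expect_equal(length(label_ids(kept)), 1)
})

test_that("segment_stack records full provenance and is monotone in content", {
  sc <- make_cell_volume(small_scene(seed = 31, n = 3, noise = FALSE))
  seg <- segment_stack(sc$grid, segmentation_config(min_voxels = 100))
  stages <- vapply(seg$label_map$provenance, function(s) s$stage, "")
  expect_equal(stages,
               c("resample_isotropic", "fuse_channels", "enhance_outlines",
                 "multi_otsu", "binarize_and_clean", "label_components",
                 "filter_small"))
  n3 <- length(label_ids(seg$label_map))
  sc4 <- make_cell_volume(small_scene(seed = 31, n = 4, noise = FALSE))
  seg4 <- segment_stack(sc4$grid, segmentation_config(min_voxels = 100))
  expect_gte(length(label_ids(seg4$label_map)), n3)
})
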