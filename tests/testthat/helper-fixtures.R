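# Fixture builders and independent oracles shared across test files.

# Digitized sphere mask of radius r voxels, centered, padded by `pad`.
sphere_mask <- function(r, pad = 4, center_offset = c(0, 0, 0)) {
  n <- 2 * r + 2 * pad + 1
  c0 <- (n + 1) / 2 + center_offset
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  array((g$z - c0[1])^2 + (g$y - c0[2])^2 + (g$x - c0[3])^2 <= r^2,
        c(n, n, n))
}

# Capsule (cylinder + hemispherical caps) mask along x, radius r voxels,
# cylinder length L voxels.
capsule_mask <- function(r, L, pad = 4) {
  nz <- 2 * r + 2 * pad + 1
  nx <- 2 * r + L + 2 * pad + 1
  cz <- (nz + 1) / 2
  x0 <- pad + r + 1; x1 <- x0 + L
  g <- expand.grid(z = 1:nz, y = 1:nz, x = 1:nx)
  t <- pmin(pmax(g$x, x0), x1)
  array((g$z - cz)^2 + (g$y - cz)^2 + (g$x - t)^2 <= r^2, c(nz, nz, nx))
}

as_label_map <- function(mask, spacing = c(1, 1, 1), connectivity = 26L) {
  label_map(array(as.integer(mask), dim(mask)), spacing_um = spacing,
            connectivity = connectivity)
}

uniform_grid <- function(mask_dims, value = 1, spacing = c(1, 1, 1)) {
  voxel_grid(array(value, mask_dims), spacing_um = spacing)
}

# Exhaustive between-class-variance search on a histogram: the independent
# multi-Otsu oracle (direct definition, no cumulative-sum shortcuts).
otsu_oracle <- function(v, k, n_bins = 64) {
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(n_bins, pmax(1, findInterval(v, edges, rightmost.closed = TRUE)))
  cnt <- tabulate(bin, n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  mu <- sum(cnt * mids) / sum(cnt)
  best <- -Inf; best_cuts <- NULL
  combos <- utils::combn(n_bins - 1, k - 1)
  for (j in seq_len(ncol(combos))) {
    cuts <- combos[, j]
    b <- c(0, cuts, n_bins)
    s <- 0
    for (ci in seq_len(k)) {
      sel <- (b[ci] + 1):b[ci + 1]
      w <- sum(cnt[sel])
      if (w == 0) next
      m <- sum(cnt[sel] * mids[sel]) / w
      s <- s + w * (m - mu)^2
    }
    if (s > best) { best <- s; best_cuts <- cuts }
  }
  edges[best_cuts + 1]
}

# Brute-force convex hull volume for small point sets: every triple that
# has all remaining points on one side is a hull facet; sum signed
# tetrahedra against the centroid.
hull_volume_oracle <- function(pts) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  vol <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
    nrm <- c(
      (b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
      (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
      (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    if (sum(nrm^2) < 1e-18) next
    d <- as.matrix(sweep(pts, 2, a)) %*% nrm
    if (all(d <= 1e-9) || all(d >= -1e-9)) {
      vol <- vol + abs(sum(nrm * (a - ctr))) / 6
    }
  }
  vol
}

# Linear-interpolation percentile computed from first principles.
percentile_oracle <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * q / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Per-truth-organelle best-match IoU of a segmentation against the scene's
# ground truth (truth resampled to the segmentation's isotropic grid).
iou_vs_truth <- function(sc, seg) {
  truth_iso <- resample_labels(sc$truth$label_map,
                               seg$label_map$spacing_um[1],
                               dim(seg$label_map$labels))$labels
  pred <- seg$label_map$labels
  tids <- sort(unique(truth_iso[truth_iso > 0]))
  vapply(tids, function(tid) {
    tmask <- truth_iso == tid
    cand <- table(pred[tmask & pred > 0])
    if (length(cand) == 0) return(0)
    best <- as.integer(names(which.max(cand)))
    pmask <- pred == best
    sum(tmask & pmask) / sum(tmask | pmask)
  }, 0)
}

# Small scene used by several tests (fast, coarse grid).
small_scene <- function(seed, n = 4, noise = TRUE, ...) {
  scene_params(n_organelles = n, cell_diameter_um = 5.5,
               spacing_um = c(0.24, 0.08, 0.08),
               psf_sigma_um = c(0.25, 0.1, 0.1),
               radius_um = 0.4, tubule_length_um = c(0.8, 1.3),
               noise = noise, seed = seed, ...)
}
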