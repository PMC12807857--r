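# Per-organelle 3D morphometry: mesh surface area, sphericity, complexity,
# roundness (equivalent diameter over major axis), solidity, intensities.

# Extract the padded binary mask and bounding-box origin of one label.
label_submask <- function(lmap, label, pad = 2L) {
  idx <- which(lmap$labels == label, arr.ind = TRUE)
  if (nrow(idx) == 0) stop(sprintf("label %d not found", label))
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  d <- hi - lo + 1L + 2L * pad
  m <- array(FALSE, d)
  m[cbind(idx[, 1] - lo[1] + pad + 1L, idx[, 2] - lo[2] + pad + 1L,
          idx[, 3] - lo[3] + pad + 1L)] <- TRUE
  list(mask = m, origin = lo - pad, coords = idx)
}

#' Mesh surface area of one labelled organelle
#'
#' Meshes the organelle's binary mask at the 0.5 level with marching
#' tetrahedra after a light Gaussian smoothing (`smooth_sigma` voxels; the
#' smoothing removes the voxelization bias that inflates the area of a
#' digitized surface by ~9%). Degenerate objects too small to survive
#' smoothing are meshed unsmoothed, so even a single voxel has positive
#' finite area.
#'
#' @param lmap A [label_map()] with isotropic spacing.
#' @param label Positive organelle id.
#' @param smooth_sigma Pre-mesh Gaussian sigma in voxels.
#' @return Surface area in µm².
#' @export
surface_area <- function(lmap, label, smooth_sigma = 0.6) {
  stopifnot(inherits(lmap, "label_map"))
  if (!is_isotropic(lmap$spacing_um)) {
    stop("surface area requires an isotropic label map; resample first")
  }
  sub <- label_submask(lmap, label)
  mesh_area(sub$mask, lmap$spacing_um, smooth_sigma)
}

mesh_area <- function(mask, spacing_um, smooth_sigma = 0.6) {
  field <- .cpp_gaussian_blur(mask * 1.0, dim(mask),
                              rep(smooth_sigma, 3))
  if (max(field) <= 0.5) field <- mask * 1.0  # too small to survive smoothing
  .cpp_isosurface_area(field, dim(mask), 0.5, as.numeric(spacing_um))
}

# Solidity on the voxel grid (the convention of standard region-property
# implementations): object voxel count over the voxel count of the
# rasterized convex hull of the object's voxel centers.
voxel_solidity <- function(mask) {
  dims <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(NA_real_)
  if (n <= 4) return(1)
  eroded <- .cpp_morph(mask, dims, ball_offsets(1), erode = TRUE)
  boundary <- which(mask & !eroded, arr.ind = TRUE)
  if (nrow(boundary) == 0) boundary <- idx
  # per-(y,x) z-extremes suffice: interior-in-z centers are redundant
  key <- paste(boundary[, 2], boundary[, 3])
  zmin <- tapply(boundary[, 1], key, min)
  zmax <- tapply(boundary[, 1], key, max)
  ky <- as.numeric(sub(" .*", "", names(zmin)))
  kx <- as.numeric(sub(".* ", "", names(zmin)))
  pts <- unique(rbind(cbind(zmin, ky, kx), cbind(zmax, ky, kx)))
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  query <- as.matrix(expand.grid(z = lo[1]:hi[1], y = lo[2]:hi[2],
                                 x = lo[3]:hi[3]))
  inside <- .cpp_in_convex_hull(pts, query, 1e-7)
  hull_n <- sum(inside)
  if (hull_n < n) return(1)  # degenerate hull (flat object)
  n / hull_n
}

#' Compute per-organelle geometric and intensity features
#'
#' For every label: voxel count, volume `V = n * spacing^3`, marching-
#' tetrahedra surface area `SA`, surface-to-volume ratio, sphericity
#' `psi = pi^(1/3) (6V)^(2/3) / SA`, complexity index `MCI = SA^3/(36 pi V^2)
#' = 1/psi^3` (1 for a sphere, larger for elongated or branched organelles),
#' roundness (equivalent-sphere diameter over the major principal-axis
#' length), compactness (solidity: `V` over convex-hull volume), and the
#' per-channel mean and integrated intensities measured on the raw
#' (resampled, unenhanced) channels over the label support.
#'
#' @param lmap A [label_map()] with isotropic spacing.
#' @param grid The [voxel_grid()] the label map was derived from (same
#'   geometry; raw resampled channels).
#' @param cell_map Optional integer 3D array of cell ids; each organelle is
#'   assigned to the cell holding the majority of its voxels.
#' @param cell_class Either a single class for the whole stack or a named
#'   vector mapping cell id to class (`"lo-cell"`, `"hi-cell"`,
#'   `"unassigned"`).
#' @param cell_id Cell id used when `cell_map` is absent.
#' @return A data frame with one row per organelle.
#' @export
compute_features <- function(lmap, grid, cell_map = NULL,
                             cell_class = "unassigned", cell_id = 1L) {
  stopifnot(inherits(lmap, "label_map"), inherits(grid, "voxel_grid"))
  if (!identical(dim(lmap$labels), dim(grid$data)[1:3])) {
    stop("label map and grid geometry differ")
  }
  if (!is_isotropic(lmap$spacing_um)) {
    stop("features require an isotropic grid; resample first")
  }
  sp <- as.numeric(lmap$spacing_um)
  voxvol <- prod(sp)
  ids <- label_ids(lmap)
  rows <- vector("list", length(ids))
  nc <- dim(grid$data)[4]
  fg <- lmap$labels > 0
  idxv <- lmap$labels[fg]
  ch_sums <- lapply(seq_len(nc), function(ci) {
    ch <- grid$data[, , , ci, drop = TRUE]
    dim(ch) <- dim(lmap$labels)
    s <- rowsum(ch[fg], idxv)
    stats::setNames(s[, 1], rownames(s))
  })
  cellv <- if (!is.null(cell_map)) cell_map[fg] else NULL
  for (j in seq_along(ids)) {
    id <- ids[j]
    sub <- label_submask(lmap, id)
    n <- nrow(sub$coords)
    V <- n * voxvol
    SA <- mesh_area(sub$mask, sp)
    psi <- pi^(1 / 3) * (6 * V)^(2 / 3) / SA
    mci <- 1 / psi^3
    # principal axes of the voxel cloud; add the voxel's own second moment
    phys <- sweep(sub$coords, 2, sp, "*")
    cv <- stats::cov(phys) * (n - 1) / max(1, n) + diag(sp^2 / 12)
    lambda1 <- max(eigen(cv, symmetric = TRUE, only.values = TRUE)$values)
    major_axis <- 2 * sqrt(5 * lambda1)
    eq_diam <- (6 * V / pi)^(1 / 3)
    roundness <- min(1, eq_diam / major_axis)
    compactness <- voxel_solidity(sub$mask)
    row <- data.frame(
      organelle_id = id, cell_id = NA_integer_, cell_class = NA_character_,
      voxel_count = n, volume_um3 = V, surface_area_um2 = SA,
      sa_v_ratio = SA / V, sphericity = psi, roundness = roundness,
      compactness = compactness, complexity = mci)
    for (ci in seq_len(nc)) {
      tot <- unname(ch_sums[[ci]][as.character(id)])
      nm <- grid$channel_names[ci]
      row[[paste0("integrated_density_", nm)]] <- tot
      row[[paste0("mean_intensity_", nm)]] <- tot / n
    }
    if (!is.null(cellv)) {
      cm <- cellv[idxv == id]
      cm <- cm[cm > 0]
      row$cell_id <- if (length(cm) > 0) {
        as.integer(names(which.max(table(cm))))
      } else NA_integer_
    } else {
      row$cell_id <- as.integer(cell_id)
    }
    rows[[j]] <- row
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  if (length(cell_class) == 1 && is.null(names(cell_class))) {
    out$cell_class <- cell_class
  } else {
    out$cell_class <- unname(cell_class[as.character(out$cell_id)])
    out$cell_class[is.na(out$cell_class)] <- "unassigned"
  }
  out
}

#' Standardize geometric features to z-scores
#'
#' Column-wise z-scoring of the geometric feature subset (intensity columns
#' are excluded by default so that downstream embeddings reflect shape
#' only). Zero-variance columns are dropped with a message. The returned
#' scaling can be re-applied to held-out rows with [apply_scaling()].
#'
#' @param features A [compute_features()] data frame (>= 2 rows).
#' @param feature_subset Columns to standardize.
#' @return A matrix with attributes `center`, `scale`, `dropped`.
#' @export
standardize_features <- function(features,
                                 feature_subset = c(
                                   "volume_um3", "surface_area_um2",
                                   "sa_v_ratio", "sphericity", "roundness",
                                   "compactness", "complexity")) {
  stopifnot(is.data.frame(features), nrow(features) >= 2)
  missing_cols <- setdiff(feature_subset, names(features))
  if (length(missing_cols) > 0) {
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "))
  }
  m <- as.matrix(features[, feature_subset, drop = FALSE])
  ctr <- colMeans(m)
  scl <- apply(m, 2, stats::sd)
  keep <- scl > 0
  if (!any(keep)) stop("all feature columns have zero variance")
  if (any(!keep)) {
    message("dropping zero-variance feature(s): ",
            paste(feature_subset[!keep], collapse = ", "))
  }
  out <- sweep(sweep(m[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  attr(out, "center") <- ctr[keep]
  attr(out, "scale") <- scl[keep]
  attr(out, "dropped") <- feature_subset[!keep]
  out
}

#' Apply a stored feature scaling to new rows
#'
#' @param scaling A matrix returned by [standardize_features()] (its
#'   `center`/`scale` attributes are used), or a list with `center` and
#'   `scale`.
#' @param features New feature data frame.
#' @return A standardized matrix on the training scale.
#' @export
apply_scaling <- function(scaling, features) {
  ctr <- attr(scaling, "center") %||% scaling$center
  scl <- attr(scaling, "scale") %||% scaling$scale
  m <- as.matrix(features[, names(ctr), drop = FALSE])
  sweep(sweep(m, 2, ctr), 2, scl, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Embed standardized features in 2D
#'
#' Deterministic 2D embedding of the standardized geometric feature matrix
#' for visualization (principal components by default, with a fixed sign
#' convention so repeated runs give identical coordinates). Coordinates are
#' unitless and intended for plotting and density maps only, not for
#' quantitative inference.
#'
#' @param mat Standardized feature matrix.
#' @param seed Unused by the PCA method; kept so that stochastic embedding
#'   methods added later share the interface.
#' @param method `"pca"` (principal components) or `"mds"` (classical
#'   metric MDS, identical to PCA on Euclidean distances).
#' @return An n-by-2 matrix of coordinates.
#' @export
embed_features <- function(mat, seed = 1L, method = c("pca", "mds")) {
  method <- match.arg(method)
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 3) {
    warning("fewer than 3 rows; embedding is degenerate")
  }
  coords <- with_seed(seed, {
    if (method == "pca") {
      p <- stats::prcomp(mat, center = FALSE, scale. = FALSE)
      k <- min(2, ncol(p$x))
      x <- p$x[, seq_len(k), drop = FALSE]
      if (k < 2) x <- cbind(x, 0)
      # sign convention: largest-|loading| entry of each axis is positive
      for (i in 1:2) {
        if (i <= ncol(p$rotation)) {
          l <- p$rotation[, i]
          if (l[which.max(abs(l))] < 0) x[, i] <- -x[, i]
        }
      }
      x
    } else {
      d <- stats::dist(mat)
      x <- stats::cmdscale(d, k = 2)
      for (i in 1:2) if (x[which.max(abs(x[, i])), i] < 0) x[, i] <- -x[, i]
      x
    }
  })
  colnames(coords) <- c("dim1", "dim2")
  coords
}

#' Gaussian kernel density on a regular 2D grid
#'
#' Evaluates a product-Gaussian kernel density estimate of embedded
#' coordinates on an `n_grid` x `n_grid` grid extending 4 bandwidths past
#' the data range; the discrete density integrates to 1 over the grid.
#'
#' @param coords n-by-2 coordinate matrix (>= 2 points).
#' @param bandwidth Per-axis bandwidth(s), or `"auto"` for Scott's rule
#'   (`sd * n^(-1/6)` per axis).
#' @param n_grid Grid resolution per axis.
#' @return A list: `x`, `y` (grid centers), `z` (density matrix), and
#'   `bandwidth`.
#' @export
kde_density <- function(coords, bandwidth = "auto", n_grid = 128L) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, nrow(coords) >= 2)
  n <- nrow(coords)
  if (identical(bandwidth, "auto")) {
    bandwidth <- apply(coords, 2, stats::sd) * n^(-1 / 6)
    bandwidth[bandwidth <= 0] <- diff(range(coords)) / 100 + 1e-8
  }
  if (length(bandwidth) == 1) bandwidth <- rep(bandwidth, 2)
  if (any(bandwidth <= 0)) stop("bandwidth must be positive (or \"auto\")")
  gx <- seq(min(coords[, 1]) - 4 * bandwidth[1],
            max(coords[, 1]) + 4 * bandwidth[1], length.out = n_grid)
  gy <- seq(min(coords[, 2]) - 4 * bandwidth[2],
            max(coords[, 2]) + 4 * bandwidth[2], length.out = n_grid)
  kx <- outer(gx, coords[, 1], function(a, b) stats::dnorm(a, b, bandwidth[1]))
  ky <- outer(gy, coords[, 2], function(a, b) stats::dnorm(a, b, bandwidth[2]))
  z <- kx %*% t(ky) / n
  list(x = gx, y = gy, z = z, bandwidth = bandwidth)
}
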