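#' Segmentation configuration
#'
#' Parameters for the organelle segmentation stack: isotropic resampling
#' target, channel fusion, outline enhancement, multi-Otsu thresholding,
#' morphological cleanup and the minimum size filter.
#'
#' @param target_spacing_um Isotropic target spacing, µm; `NULL` uses the
#'   finest input spacing.
#' @param fusion_channels Channels fused for segmentation; `NULL` = all.
#' @param feather_sigma_um Gaussian scale of the outline-enhancement term.
#' @param feather_alpha Weight of the outline term (0 disables it).
#' @param otsu_classes Number of intensity classes `k >= 2`.
#' @param foreground_classes How many of the top classes are foreground.
#' @param morph_ops Ordered morphological operations, a subset of
#'   `"closing"`, `"fill"`, `"erosion"` (ball structuring elements).
#' @param morph_radius Structuring-element radius in voxels.
#' @param min_voxels Components with fewer voxels than this are removed
#'   (strictly smaller; a component of exactly `min_voxels` is kept).
#' @param connectivity Labelling connectivity, 6 or 26.
#' @param interpolation_order Resampling order: 1 (trilinear) or 0 (nearest).
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(target_spacing_um = NULL,
                                fusion_channels = NULL,
                                feather_sigma_um = 0.1,
                                feather_alpha = 0.5,
                                otsu_classes = 3L,
                                foreground_classes = 1L,
                                morph_ops = c("closing", "fill", "erosion"),
                                morph_radius = 1L,
                                min_voxels = 500L,
                                connectivity = 26L,
                                interpolation_order = 1L) {
  stopifnot(otsu_classes >= 2, foreground_classes >= 1,
            foreground_classes < otsu_classes, morph_radius >= 1,
            min_voxels >= 1, connectivity %in% c(6, 26),
            interpolation_order %in% c(0, 1),
            all(morph_ops %in% c("closing", "fill", "erosion")))
  structure(as.list(environment()), class = "segmentation_config")
}

#' Resample a grid to isotropic voxels
#'
#' Upscales every channel to a common (typically the finest) spacing with
#' trilinear interpolation, clamping intensities at 0 and preserving the
#' physical extent to within one voxel per axis. Voxel centers are aligned
#' in physical space.
#'
#' @param grid A [voxel_grid()].
#' @param target_spacing_um Isotropic target spacing, µm; must not be
#'   coarser than the finest input spacing. `NULL` uses the finest input
#'   spacing.
#' @param order 1 (trilinear, default) or 0 (nearest neighbour).
#' @return A [voxel_grid()] with equal spacing on all axes.
#' @export
resample_isotropic <- function(grid, target_spacing_um = NULL, order = 1L) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(target_spacing_um)) target_spacing_um <- min(grid$spacing_um)
  stop_if_not_positive(target_spacing_um, "target_spacing_um")
  if (target_spacing_um > min(grid$spacing_um) * (1 + 1e-9)) {
    stop("`target_spacing_um` must be <= the finest input spacing (upscaling only)")
  }
  d <- dim(grid$data)
  out_dims <- as.integer(round(d[1:3] * grid$spacing_um / target_spacing_um))
  out_dims <- pmax(out_dims, 1L)
  sp_out <- rep(target_spacing_um, 3)
  arr <- array(0, c(out_dims, d[4]))
  for (ci in seq_len(d[4])) {
    ch <- grid$data[, , , ci, drop = TRUE]
    dim(ch) <- d[1:3]
    if (order == 0L) {
      zi <- pmin(d[1], pmax(1, round((seq_len(out_dims[1]) - 0.5) *
                                       sp_out[1] / grid$spacing_um[1] + 0.5)))
      yi <- pmin(d[2], pmax(1, round((seq_len(out_dims[2]) - 0.5) *
                                       sp_out[2] / grid$spacing_um[2] + 0.5)))
      xi <- pmin(d[3], pmax(1, round((seq_len(out_dims[3]) - 0.5) *
                                       sp_out[3] / grid$spacing_um[3] + 0.5)))
      arr[, , , ci] <- ch[zi, yi, xi]
    } else {
      arr[, , , ci] <- .cpp_resample_trilinear(
        ch, dim(ch), out_dims, as.numeric(grid$spacing_um), sp_out)
    }
  }
  voxel_grid(arr, spacing_um = sp_out, channel_names = grid$channel_names)
}

#' Resample a label map to an isotropic grid
#'
#' Nearest-neighbour resampling of integer labels onto an isotropic grid
#' with voxel centers aligned in physical space — used, for example, to
#' compare a ground-truth label map defined on the anisotropic acquisition
#' grid with a segmentation computed on the isotropic grid.
#'
#' @param lmap A [label_map()].
#' @param target_spacing_um Isotropic target spacing, µm.
#' @param target_dims Optional output dimensions (z, y, x); defaults to
#'   `round(dims * spacing / target)`.
#' @return A [label_map()] on the isotropic grid.
#' @export
resample_labels <- function(lmap, target_spacing_um, target_dims = NULL) {
  stopifnot(inherits(lmap, "label_map"))
  stop_if_not_positive(target_spacing_um, "target_spacing_um")
  d <- dim(lmap$labels)
  if (is.null(target_dims)) {
    target_dims <- as.integer(round(d * lmap$spacing_um / target_spacing_um))
  }
  nn <- function(n_out, n_in, sp_in) {
    pmin(n_in, pmax(1L, as.integer(round(
      (seq_len(n_out) - 0.5) * target_spacing_um / sp_in + 0.5))))
  }
  labels <- lmap$labels[nn(target_dims[1], d[1], lmap$spacing_um[1]),
                        nn(target_dims[2], d[2], lmap$spacing_um[2]),
                        nn(target_dims[3], d[3], lmap$spacing_um[3])]
  out <- label_map(labels, spacing_um = rep(target_spacing_um, 3),
                   connectivity = lmap$connectivity,
                   provenance = lmap$provenance)
  add_provenance(out, "resample_labels",
                 list(target_spacing_um = target_spacing_um))
}

#' Fuse channels into one segmentation volume
#'
#' Min–max normalizes each named channel to \[0, 1\] and takes the voxelwise
#' maximum, so an organelle visible in any channel (e.g. only in the
#' age-label channel) contributes to the fused volume.
#'
#' @param grid A [voxel_grid()].
#' @param channels Channel names to fuse; `NULL` fuses all.
#' @return A 3D array in \[0, 1\].
#' @export
fuse_channels <- function(grid, channels = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(channels)) channels <- grid$channel_names
  stopifnot(length(channels) >= 1)
  fused <- NULL
  for (ch in channels) {
    v <- get_channel(grid, ch)
    rng <- range(v)
    v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
    fused <- if (is.null(fused)) v else pmax(fused, v)
  }
  array(fused, dim(grid$data)[1:3])
}

#' Enhance organelle outlines
#'
#' Adds a Gaussian-gradient-magnitude term to the volume —
#' `vol + alpha * |grad(G_sigma * vol)| / max(|grad|)` — then rescales to
#' \[0, 1\]. `alpha = 0` returns the input unchanged. This boosts organelle
#' outlines ahead of thresholding.
#'
#' @param vol 3D array in \[0, 1\].
#' @param sigma_um Gaussian derivative scale, µm (>= 0).
#' @param alpha Weight of the outline term.
#' @param spacing_um Voxel spacing (z, y, x), µm.
#' @return A 3D array in \[0, 1\].
#' @export
enhance_outlines <- function(vol, sigma_um = 0.1, alpha = 0.5,
                             spacing_um) {
  stopifnot(length(dim(vol)) == 3, alpha >= 0)
  if (sigma_um < 0) stop("`sigma_um` must be nonnegative")
  if (alpha == 0) return(vol)
  sigma_vox <- sigma_um / spacing_um
  # normalized convolution: renormalize the zero-padded blur at the borders
  # so that a constant volume stays constant (zero gradient everywhere)
  sm <- .cpp_gaussian_blur(vol, dim(vol), sigma_vox)
  w <- .cpp_gaussian_blur(array(1, dim(vol)), dim(vol), sigma_vox)
  sm <- sm / w
  grad2 <- array(0, dim(vol))
  for (axis in 1:3) {
    d <- dim(vol)
    g <- array(0, d)
    n <- d[axis]
    if (n >= 3) {
      # central differences along `axis`, one-sided at the borders
      perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
      a <- aperm(sm, perm)
      da <- a
      da[2:(n - 1), , ] <- (a[3:n, , ] - a[1:(n - 2), , ]) / 2
      da[1, , ] <- a[2, , ] - a[1, , ]
      da[n, , ] <- a[n, , ] - a[n - 1, , ]
      g <- aperm(da, order(perm)) / spacing_um[axis]
    }
    grad2 <- grad2 + g^2
  }
  gm <- sqrt(grad2)
  mx <- max(gm)
  if (mx > 0) gm <- gm / mx
  out <- vol + alpha * gm
  rng <- range(out)
  if (diff(rng) > 0) (out - rng[1]) / diff(rng) else out * 0
}

#' Multi-Otsu thresholds
#'
#' Chooses `k - 1` ascending thresholds maximizing the between-class
#' variance of the intensity histogram over `k` classes (exhaustive search
#' over histogram bin boundaries; ties broken toward the lowest threshold
#' set). With `k = 2` this is classical Otsu thresholding.
#'
#' @param vol Numeric array or vector of intensities with at least `k`
#'   distinct values.
#' @param k Number of classes (2–4).
#' @param n_bins Histogram resolution.
#' @return Numeric vector of `k - 1` ascending thresholds (bin boundaries).
#' @export
multi_otsu_thresholds <- function(vol, k = 3L, n_bins = 128L) {
  v <- as.numeric(vol)
  v <- v[is.finite(v)]
  k <- as.integer(k)
  stopifnot(k >= 2, k <= 4, n_bins >= k)
  if (length(unique(v)) < k) {
    stop(sprintf("need at least %d distinct intensity values for k = %d", k, k))
  }
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(n_bins, pmax(1L, findInterval(v, edges, rightmost.closed = TRUE)))
  cnt <- tabulate(bin, nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  W <- cumsum(cnt)
  M <- cumsum(cnt * mids)
  N <- W[n_bins]
  # class statistic: sum over classes of w_c * mu_c^2 (maximizing this is
  # equivalent to maximizing between-class variance)
  cw <- function(a, b) W[b] - if (a > 0) W[a] else 0   # count in bins (a, b]
  cm <- function(a, b) M[b] - if (a > 0) M[a] else 0
  score2 <- function(cuts) {
    bounds <- c(0L, cuts, n_bins)
    s <- 0
    for (ci in seq_len(length(bounds) - 1)) {
      w <- cw(bounds[ci], bounds[ci + 1])
      if (w > 0) s <- s + cm(bounds[ci], bounds[ci + 1])^2 / w
    }
    s
  }
  best <- -Inf
  best_cuts <- NULL
  combos <- utils::combn(n_bins - 1L, k - 1L)
  for (j in seq_len(ncol(combos))) {
    cuts <- combos[, j]
    s <- score2(cuts)
    if (s > best) {  # strict: ties keep the lowest threshold set
      best <- s
      best_cuts <- cuts
    }
  }
  edges[best_cuts + 1L]
}

#' Binarize and morphologically clean a volume
#'
#' Thresholds the volume (foreground = voxels strictly above the threshold
#' delimiting the top `foreground_classes` classes), then applies the
#' configured morphological operations with ball structuring elements —
#' default: closing (radius 1), 3D hole filling, then erosion (radius 1).
#'
#' @param vol 3D numeric array.
#' @param thresholds Ascending thresholds from [multi_otsu_thresholds()].
#' @param config A [segmentation_config()].
#' @return A logical 3D array. If cleanup empties the mask a warning is
#'   raised and the empty mask returned.
#' @export
binarize_and_clean <- function(vol, thresholds, config = segmentation_config()) {
  stopifnot(length(dim(vol)) == 3, !is.unsorted(thresholds))
  fg_cut <- thresholds[length(thresholds) - config$foreground_classes + 1L]
  mask <- vol > fg_cut
  dims <- dim(vol)
  r <- config$morph_radius
  off <- ball_offsets(r)
  for (op in config$morph_ops) {
    if (!any(mask)) break
    mask <- switch(
      op,
      closing = {
        pd <- dims + 2L * r
        padded <- array(FALSE, pd)
        padded[(r + 1):(r + dims[1]), (r + 1):(r + dims[2]),
               (r + 1):(r + dims[3])] <- mask
        padded <- .cpp_morph(padded, pd, off, erode = FALSE)
        padded <- .cpp_morph(padded, pd, off, erode = TRUE)
        padded[(r + 1):(r + dims[1]), (r + 1):(r + dims[2]),
               (r + 1):(r + dims[3])]
      },
      fill = .cpp_fill_holes(mask, dims),
      erosion = .cpp_morph(mask, dims, off, erode = TRUE)
    )
    dim(mask) <- dims
  }
  if (!any(mask)) {
    warning("mask is empty after thresholding/cleanup")
  }
  mask
}

#' Label connected components
#'
#' Assigns a unique positive id to every maximal connected foreground
#' component at the stated connectivity.
#'
#' @param mask Logical 3D array.
#' @param spacing_um Voxel spacing (z, y, x), µm.
#' @param connectivity 26 (default) or 6.
#' @param provenance Optional provenance list carried over from earlier
#'   stages.
#' @return A [label_map()].
#' @export
label_components <- function(mask, spacing_um, connectivity = 26L,
                             provenance = list()) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  labels <- .cpp_label_components(mask, dim(mask), as.integer(connectivity))
  lm <- label_map(labels, spacing_um = spacing_um,
                  connectivity = connectivity, provenance = provenance)
  add_provenance(lm, "label_components",
                 list(connectivity = as.integer(connectivity)))
}

#' Remove small components
#'
#' Components strictly smaller than `min_voxels` voxels are treated as
#' noise and set to background; components of exactly `min_voxels` voxels
#' are retained. Surviving ids are not renumbered.
#'
#' @param lmap A [label_map()].
#' @param min_voxels Minimum voxel count (default 500).
#' @return A filtered [label_map()].
#' @export
filter_small <- function(lmap, min_voxels = 500L) {
  stopifnot(inherits(lmap, "label_map"), min_voxels >= 1)
  m <- max(lmap$labels)
  if (m > 0) {
    sizes <- .cpp_label_sizes(lmap$labels, m)
    drop <- which(sizes > 0 & sizes < min_voxels)
    if (length(drop) > 0) {
      lmap$labels[lmap$labels %in% drop] <- 0L
    }
  }
  add_provenance(lmap, "filter_small", list(min_voxels = as.integer(min_voxels)))
}

#' Run the full segmentation stack on a grid
#'
#' Isotropic resampling, channel fusion, outline enhancement, multi-Otsu
#' thresholding, morphological cleanup, connected-component labelling and
#' the small-component filter, with every stage and its parameters recorded
#' in the label map's provenance.
#'
#' @param grid A [voxel_grid()].
#' @param config A [segmentation_config()].
#' @return A list: `label_map` (the segmentation), `grid_iso` (the
#'   resampled grid whose raw channels intensity features should be
#'   measured on), `thresholds`.
#' @export
segment_stack <- function(grid, config = segmentation_config()) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(config, "segmentation_config"))
  target <- if (is.null(config$target_spacing_um)) min(grid$spacing_um) else
    config$target_spacing_um
  grid_iso <- resample_isotropic(grid, target, order = config$interpolation_order)
  fused <- fuse_channels(grid_iso, config$fusion_channels)
  enhanced <- enhance_outlines(fused, sigma_um = config$feather_sigma_um,
                               alpha = config$feather_alpha,
                               spacing_um = grid_iso$spacing_um)
  thresholds <- multi_otsu_thresholds(enhanced, k = config$otsu_classes)
  mask <- binarize_and_clean(enhanced, thresholds, config)
  prov <- list(
    list(stage = "resample_isotropic", target_spacing_um = target,
         order = config$interpolation_order),
    list(stage = "fuse_channels",
         channels = if (is.null(config$fusion_channels)) grid$channel_names
         else config$fusion_channels),
    list(stage = "enhance_outlines", sigma_um = config$feather_sigma_um,
         alpha = config$feather_alpha),
    list(stage = "multi_otsu", k = config$otsu_classes,
         thresholds = thresholds,
         foreground_classes = config$foreground_classes),
    list(stage = "binarize_and_clean", morph_ops = config$morph_ops,
         morph_radius = config$morph_radius)
  )
  lmap <- label_components(mask, spacing_um = grid_iso$spacing_um,
                           connectivity = config$connectivity,
                           provenance = prov)
  lmap <- filter_small(lmap, config$min_voxels)
  list(label_map = lmap, grid_iso = grid_iso, thresholds = thresholds)
}
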