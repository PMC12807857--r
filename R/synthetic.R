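#' Parameters for a synthetic single-cell organelle scene
#'
#' Describes the acquisition the generator emulates: an ellipsoidal cell
#' containing non-overlapping tubular (capsule) and punctate (sphere)
#' organelles, imaged in a structural channel (`Tom20`, all organelles) and
#' an age-label channel (`SnapTag`, bright for "old" organelles, dim for
#' "young"), on an anisotropic voxel grid (z coarser than xy), with a
#' separable Gaussian PSF, Poisson photon noise and Gaussian read noise.
#'
#' @param n_organelles Number of organelles to place.
#' @param shape_mix Fraction of organelles that are tubules (capsules);
#'   the rest are spheres.
#' @param radius_um Typical organelle radius, µm (jittered by ±20%).
#' @param tubule_length_um Length-2 range of tubule cylinder lengths, µm.
#' @param old_fraction Fraction of organelles drawn from the bright ("old")
#'   age-label component.
#' @param intensity_old,intensity_young Mean age-channel photon rate per
#'   voxel for old and young organelles.
#' @param structural_intensity Photon rate per voxel in the structural
#'   channel (all organelles).
#' @param background Background photon rate per voxel.
#' @param psf_sigma_um Per-axis (z, y, x) Gaussian PSF sigmas, µm.
#' @param spacing_um Per-axis (z, y, x) voxel spacing, µm; z must not be
#'   finer than xy.
#' @param cell_diameter_um Cell diameter in xy, µm (the cell is an ellipsoid
#'   flattened to 60% of this in z).
#' @param min_gap_um Minimum surface-to-surface gap between organelles, µm.
#' @param noise If `TRUE`, apply Poisson noise plus Gaussian read noise.
#' @param read_noise_sd Standard deviation of the additive read noise.
#' @param include_nuclear If `TRUE`, add a central nuclear channel.
#' @param seed Integer RNG seed; identical parameters and seed give
#'   bit-identical output.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(n_organelles = 10,
                         shape_mix = 0.5,
                         radius_um = 0.45,
                         tubule_length_um = c(1.0, 2.2),
                         old_fraction = 0.5,
                         intensity_old = 80,
                         intensity_young = 15,
                         structural_intensity = 60,
                         background = 2,
                         psf_sigma_um = c(0.2, 0.08, 0.08),
                         spacing_um = c(0.13, 0.13 / 3, 0.13 / 3),
                         cell_diameter_um = 5.5,
                         min_gap_um = 0.3,
                         noise = TRUE,
                         read_noise_sd = 1.5,
                         include_nuclear = FALSE,
                         seed = NULL) {
  stop_if_not_scalar_fraction(shape_mix, "shape_mix")
  stop_if_not_scalar_fraction(old_fraction, "old_fraction")
  stop_if_not_positive(radius_um, "radius_um")
  stop_if_not_positive(tubule_length_um, "tubule_length_um")
  stop_if_not_positive(spacing_um, "spacing_um")
  stop_if_not_positive(cell_diameter_um, "cell_diameter_um")
  stopifnot(n_organelles >= 0, length(spacing_um) == 3,
            length(psf_sigma_um) == 3, length(tubule_length_um) == 2,
            intensity_old >= 0, intensity_young >= 0, background >= 0,
            read_noise_sd >= 0)
  if (spacing_um[1] < max(spacing_um[2:3])) {
    stop("z spacing must be >= xy spacing (anisotropic or isotropic stack)")
  }
  structure(as.list(environment()), class = "scene_params")
}

# Minimum distance between two 3D segments (p1-q1) and (p2-q2).
segment_distance <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  eps <- 1e-12
  if (a <= eps && e <= eps) return(sqrt(sum(r * r)))
  if (a <= eps) {
    s <- 0; t <- min(1, max(0, f / e))
  } else {
    c1 <- sum(d1 * r)
    if (e <= eps) {
      t <- 0; s <- min(1, max(0, -c1 / a))
    } else {
      b <- sum(d1 * d2)
      denom <- a * e - b * b
      s <- if (denom > eps) min(1, max(0, (b * f - c1 * e) / denom)) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(1, max(0, -c1 / a)) }
      else if (t > 1) { t <- 1; s <- min(1, max(0, (b - c1) / a)) }
    }
  }
  v <- (p1 + s * d1) - (p2 + t * d2)
  sqrt(sum(v * v))
}

# Paint capsule/sphere organelles into an integer label array.
# `organelles` columns: id, p*(segment start), q*(segment end), radius_um.
paint_organelles <- function(organelles, dims, spacing_um) {
  labels <- array(0L, dims)
  if (nrow(organelles) == 0) return(labels)
  axes <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * spacing_um[a])
  for (i in seq_len(nrow(organelles))) {
    o <- organelles[i, ]
    p <- c(o$pz, o$py, o$px); q <- c(o$qz, o$qy, o$qx); r <- o$radius_um
    lo <- pmin(p, q) - r - spacing_um; hi <- pmax(p, q) + r + spacing_um
    rng <- lapply(1:3, function(a) {
      which(axes[[a]] >= lo[a] & axes[[a]] <= hi[a])
    })
    if (any(lengths(rng) == 0)) next
    zc <- axes[[1]][rng[[1]]]; yc <- axes[[2]][rng[[2]]]; xc <- axes[[3]][rng[[3]]]
    d <- q - p; len2 <- sum(d * d)
    gz <- array(zc, c(length(zc), length(yc), length(xc)))
    gy <- aperm(array(yc, c(length(yc), length(zc), length(xc))), c(2, 1, 3))
    gx <- aperm(array(xc, c(length(xc), length(zc), length(yc))), c(2, 3, 1))
    if (len2 < 1e-12) {
      dist2 <- (gz - p[1])^2 + (gy - p[2])^2 + (gx - p[3])^2
    } else {
      t <- ((gz - p[1]) * d[1] + (gy - p[2]) * d[2] + (gx - p[3]) * d[3]) / len2
      t <- pmin(1, pmax(0, t))
      dist2 <- (gz - (p[1] + t * d[1]))^2 + (gy - (p[2] + t * d[2]))^2 +
        (gx - (p[3] + t * d[3]))^2
    }
    inside <- dist2 <= r^2
    sub <- labels[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    sub[inside] <- o$id
    labels[rng[[1]], rng[[2]], rng[[3]]] <- sub
  }
  labels
}

# Sample non-overlapping organelle geometry inside an ellipsoidal cell.
place_organelles <- function(params, semi_axes, center, strata = NULL) {
  n <- params$n_organelles
  cols <- c("id", "shape", "age_class", "radius_um", "length_um",
            "pz", "py", "px", "qz", "qy", "qx")
  out <- as.data.frame(matrix(numeric(0), 0, length(cols),
                              dimnames = list(NULL, cols)))
  if (n == 0) return(out)
  is_tubule <- stats::runif(n) < params$shape_mix
  is_old <- stats::runif(n) < params$old_fraction
  placed <- list()
  for (i in seq_len(n)) {
    r <- params$radius_um * stats::runif(1, 0.8, 1.2)
    len <- if (is_tubule[i]) {
      stats::runif(1, params$tubule_length_um[1], params$tubule_length_um[2])
    } else 0
    ok <- FALSE
    for (try in seq_len(500)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      # bias tubules toward the xy plane (thin cells)
      if (len > 0) u[1] <- u[1] * 0.3
      u <- u / sqrt(sum(u^2))
      ctr <- center + (stats::runif(3, -1, 1)) * (semi_axes - r - 0.1)
      p <- ctr - u * len / 2; q <- ctr + u * len / 2
      inside <- function(pt) {
        sum(((pt - center) / pmax(semi_axes - r - 0.05, 0.01))^2) <= 1
      }
      if (!inside(p) || !inside(q)) next
      clash <- FALSE
      for (ex in placed) {
        dmin <- segment_distance(p, q, ex$p, ex$q)
        if (dmin < r + ex$r + params$min_gap_um) { clash <- TRUE; break }
      }
      if (!clash) {
        placed[[i]] <- list(p = p, q = q, r = r)
        out[i, ] <- NA
        out$id[i] <- i
        out$shape[i] <- if (len > 0) "tubule" else "sphere"
        out$age_class[i] <- if (is_old[i]) "old" else "young"
        out$radius_um[i] <- r
        out$length_um[i] <- len
        out[i, c("pz", "py", "px")] <- p
        out[i, c("qz", "qy", "qx")] <- q
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf(paste0("could not place organelle %d of %d after 500 ",
                          "attempts; the scene is too dense (reduce ",
                          "n_organelles or organelle size)"), i, n),
           call. = FALSE)
    }
  }
  out$shape <- as.character(out$shape)
  out$age_class <- as.character(out$age_class)
  out
}

apply_noise <- function(rate, read_noise_sd) {
  n <- length(rate)
  noisy <- stats::rpois(n, lambda = as.vector(rate)) +
    stats::rnorm(n, 0, read_noise_sd)
  noisy[noisy < 0] <- 0
  array(noisy, dim(rate))
}

#' Generate a ground-truthed synthetic cell stack
#'
#' Places non-overlapping organelles (capsule tubules and spheres) inside an
#' ellipsoidal cell, renders a structural and an age-label channel through a
#' separable Gaussian PSF, and optionally applies Poisson photon noise plus
#' Gaussian read noise. The noise-free truth (label map on the generation
#' grid and per-organelle records) is returned alongside the image.
#'
#' @param params A [scene_params()] object.
#' @return A list with elements `grid` (a [voxel_grid()]) and `truth`
#'   (class `ground_truth`: `label_map`, `organelles` data frame with true
#'   volumes and emitted intensities, and the generating parameters).
#' @examples
#' sc <- make_cell_volume(scene_params(n_organelles = 3, seed = 1,
#'   cell_diameter_um = 3.5, spacing_um = c(0.24, 0.08, 0.08)))
#' sc$grid
#' sc$truth$organelles$true_volume_um3
#' @export
make_cell_volume <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed, {
    semi_axes <- c(0.6, 1, 1) * params$cell_diameter_um / 2
    pad <- 0.6
    extent <- 2 * (semi_axes + pad)
    dims <- pmax(4L, as.integer(ceiling(extent / params$spacing_um)))
    center <- extent / 2
    org <- place_organelles(params, semi_axes, center)
    labels <- paint_organelles(org, dims, params$spacing_um)
    sigma_vox <- params$psf_sigma_um / params$spacing_um

    age_int <- if (!is.null(params$age_intensities)) {
      params$age_intensities
    } else {
      ifelse(org$age_class == "old", params$intensity_old,
             params$intensity_young)
    }
    voxvol <- prod(params$spacing_um)
    counts <- if (nrow(org) > 0) {
      tabulate(labels[labels > 0], nbins = nrow(org))
    } else integer(0)
    org$voxel_count <- counts
    org$true_volume_um3 <- counts * voxvol
    org$age_intensity <- if (nrow(org) > 0) age_int else numeric(0)
    org$emitted_structural <- counts * params$structural_intensity
    org$emitted_age <- counts * org$age_intensity

    structural <- array(params$background, dims)
    agech <- array(params$background, dims)
    if (nrow(org) > 0) {
      fg <- labels > 0
      structural[fg] <- structural[fg] + params$structural_intensity
      agech[fg] <- agech[fg] + age_int[labels[fg]]
    }
    channels <- list(Tom20 = structural, SnapTag = agech)
    if (isTRUE(params$include_nuclear)) {
      axes <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) *
                       params$spacing_um[a])
      nuc_semi <- semi_axes * 0.45
      gz <- array(axes[[1]], dims)
      gy <- aperm(array(axes[[2]], dims[c(2, 1, 3)]), c(2, 1, 3))
      gx <- aperm(array(axes[[3]], dims[c(3, 1, 2)]), c(2, 3, 1))
      nuc <- ((gz - center[1]) / nuc_semi[1])^2 +
        ((gy - center[2]) / nuc_semi[2])^2 +
        ((gx - center[3]) / nuc_semi[3])^2 <= 1
      channels$DAPI <- array(params$background, dims) + 40 * nuc
    }
    channels <- lapply(channels, function(ch) {
      ch <- .cpp_gaussian_blur(ch, dims, sigma_vox)
      if (isTRUE(params$noise)) ch <- apply_noise(ch, params$read_noise_sd)
      ch
    })
    arr <- array(0, c(dims, length(channels)))
    for (i in seq_along(channels)) arr[, , , i] <- channels[[i]]
    grid <- voxel_grid(arr, spacing_um = params$spacing_um,
                       channel_names = names(channels))
    truth <- structure(
      list(label_map = label_map(labels, spacing_um = params$spacing_um,
                                 connectivity = 26L,
                                 provenance = list(list(stage = "synthetic_truth"))),
           organelles = org, params = params),
      class = "ground_truth")
    list(grid = grid, truth = truth)
  })
}

#' Generate a synthetic mitotic daughter pair
#'
#' Builds two disjoint ellipsoidal daughter masks joined by a thin bridge
#' region (excluded from both), and distributes `total_cargo` photons of a
#' cargo channel over mirrored puncta so that the expected integrated
#' density in daughter 1 is `f * total_cargo`. Because daughter 2's puncta
#' mirror daughter 1's, PSF losses cancel and the noise-free asymmetry
#' score is exactly `2f - 1`.
#'
#' @param f Partition fraction of cargo inherited by daughter 1, in
#'   \[0, 1\].
#' @param total_cargo Total emitted cargo photons across both daughters.
#' @param noise Apply Poisson + read noise?
#' @param seed Integer RNG seed.
#' @param reference_fraction Optional partition fraction for a second,
#'   reference channel (e.g. a CD8-like surface marker) rendered uniformly
#'   over each daughter mask; `NULL` omits the channel.
#' @param spacing_um Voxel spacing (z, y, x), µm.
#' @param daughter_radius_um Daughter xy radius, µm (z semi-axis is 60%).
#' @param n_puncta Cargo puncta per daughter.
#' @param punctum_radius_um Punctum radius, µm.
#' @param psf_sigma_um PSF sigmas (z, y, x), µm.
#' @param read_noise_sd Read-noise standard deviation.
#' @return A list: `grid`, `mask1`, `mask2` (logical arrays), and `truth`
#'   (`f`, `total_cargo`, `expected_score = 2f - 1`, `degenerate` flag).
#' @examples
#' pr <- make_daughter_pair(0.6, total_cargo = 1e4, noise = FALSE, seed = 1)
#' p1 <- integrated_density(pr$grid, pr$mask1, "cargo")
#' p2 <- integrated_density(pr$grid, pr$mask2, "cargo")
#' asymmetry_score(max(p1, p2), min(p1, p2))
#' @export
make_daughter_pair <- function(f, total_cargo = 2e5, noise = TRUE,
                               seed = NULL, reference_fraction = NULL,
                               spacing_um = c(0.3, 0.1, 0.1),
                               daughter_radius_um = 2,
                               n_puncta = 5, punctum_radius_um = 0.3,
                               psf_sigma_um = c(0.25, 0.1, 0.1),
                               read_noise_sd = 1.5) {
  stop_if_not_scalar_fraction(f, "f")
  stopifnot(total_cargo >= 0)
  with_seed(seed, {
    r <- daughter_radius_um
    semi <- c(0.6 * r, r, r)
    bridge_half_um <- 0.5
    pad <- 0.8
    centers_dx <- 2 * semi[3] - 0.4  # slight overlap, carved by the bridge
    extent <- c(2 * (semi[1] + pad), 2 * (semi[2] + pad),
                centers_dx + 2 * (semi[3] + pad))
    dims <- as.integer(ceiling(extent / spacing_um))
    axes <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * spacing_um[a])
    cz <- extent[1] / 2; cy <- extent[2] / 2
    cx1 <- extent[3] / 2 - centers_dx / 2
    cx2 <- extent[3] / 2 + centers_dx / 2
    xmid <- extent[3] / 2
    gz <- array(axes[[1]], dims)
    gy <- aperm(array(axes[[2]], dims[c(2, 1, 3)]), c(2, 1, 3))
    gx <- aperm(array(axes[[3]], dims[c(3, 1, 2)]), c(2, 3, 1))
    in_ell <- function(cx) {
      ((gz - cz) / semi[1])^2 + ((gy - cy) / semi[2])^2 +
        ((gx - cx) / semi[3])^2 <= 1
    }
    bridge <- abs(gx - xmid) < bridge_half_um
    mask1 <- in_ell(cx1) & !bridge & gx < xmid
    mask2 <- in_ell(cx2) & !bridge & gx > xmid

    # mirrored puncta: daughter 2 reflects daughter 1 through the midplane
    inner <- semi * 0.5
    pts <- matrix(NA_real_, n_puncta, 3)
    k <- 0
    while (k < n_puncta) {
      cand <- c(cz, cy, cx1) + stats::runif(3, -1, 1) * inner
      if (sum(((cand - c(cz, cy, cx1)) / inner)^2) > 1) next
      if (k > 0 && any(sqrt(colSums((t(pts[seq_len(k), , drop = FALSE]) -
                                       cand)^2)) < 2.2 * punctum_radius_um))
        next
      k <- k + 1
      pts[k, ] <- cand
    }
    org1 <- data.frame(id = seq_len(n_puncta), pz = pts[, 1], py = pts[, 2],
                       px = pts[, 3], qz = pts[, 1], qy = pts[, 2],
                       qx = pts[, 3], radius_um = punctum_radius_um)
    org2 <- org1
    org2$id <- org2$id + n_puncta
    org2$px <- 2 * xmid - org1$px
    org2$qx <- 2 * xmid - org1$qx
    lab <- paint_organelles(rbind(org1, org2), dims, spacing_um)
    n1 <- sum(lab > 0 & lab <= n_puncta)
    n2 <- sum(lab > n_puncta)
    cargo <- array(0, dims)
    if (total_cargo > 0) {
      if (n1 > 0) cargo[lab > 0 & lab <= n_puncta] <- f * total_cargo / n1
      if (n2 > 0) cargo[lab > n_puncta] <- (1 - f) * total_cargo / n2
    }
    sigma_vox <- psf_sigma_um / spacing_um
    channels <- list(cargo = .cpp_gaussian_blur(cargo, dims, sigma_vox))
    if (!is.null(reference_fraction)) {
      stop_if_not_scalar_fraction(reference_fraction, "reference_fraction")
      ref <- array(0, dims)
      ref[mask1] <- reference_fraction / sum(mask1)
      ref[mask2] <- (1 - reference_fraction) / sum(mask2)
      channels$reference <- .cpp_gaussian_blur(ref * 1e5, dims, sigma_vox)
    }
    if (isTRUE(noise)) {
      channels <- lapply(channels, apply_noise, read_noise_sd = read_noise_sd)
    }
    arr <- array(0, c(dims, length(channels)))
    for (i in seq_along(channels)) arr[, , , i] <- channels[[i]]
    grid <- voxel_grid(arr, spacing_um = spacing_um,
                       channel_names = names(channels))
    truth <- list(f = f, total_cargo = total_cargo,
                  expected_score = 2 * f - 1,
                  degenerate = total_cargo == 0)
    list(grid = grid, mask1 = mask1, mask2 = mask2, truth = truth)
  })
}

#' Generate a synthetic cell population with planted age-label strata
#'
#' Emulates the reference populations used by the age-stratification rule:
#' `lo`-class cells contain only dim-label organelles, while `hi`-class
#' cells contain a planted mixture of `lo`, `mid` and `hi` intensity
#' components in fixed proportions. The planted stratum and planted mean
#' age-label intensity of every organelle are recorded in the truth.
#'
#' @param n_lo_cells,n_hi_cells Cell counts per class (each >= 1 unless the
#'   other is positive).
#' @param intensity_model List with per-stratum mean photon rates
#'   (`lo_mean`, `mid_mean`, `hi_mean`), log-normal spread `sdlog`, and
#'   `hi_props`, the planted stratum proportions inside hi-class cells.
#' @param scene A [scene_params()] template used for every cell (its
#'   `old_fraction` and age intensities are overridden by the model).
#' @param seed Integer RNG seed.
#' @return A list of class `population`: one element per cell with `grid`,
#'   `truth` (organelles gain `planted_stratum`) and `cell_class`
#'   (`"lo-cell"` or `"hi-cell"`).
#' @export
make_population <- function(n_lo_cells, n_hi_cells,
                            intensity_model = list(
                              lo_mean = 15, mid_mean = 120, hi_mean = 400,
                              sdlog = 0.12,
                              hi_props = c(lo = 0.25, mid = 0.5, hi = 0.25)),
                            scene = scene_params(n_organelles = 12, cell_diameter_um = 7.5),
                            seed = NULL) {
  stopifnot(n_lo_cells >= 0, n_hi_cells >= 0, n_lo_cells + n_hi_cells >= 1)
  if (n_lo_cells < 1) {
    stop("at least one lo-class reference cell is required")
  }
  im <- intensity_model
  stopifnot(all(c("lo_mean", "mid_mean", "hi_mean", "sdlog", "hi_props") %in%
                  names(im)))
  props <- im$hi_props / sum(im$hi_props)
  with_seed(seed, {
    classes <- c(rep("lo-cell", n_lo_cells), rep("hi-cell", n_hi_cells))
    cells <- vector("list", length(classes))
    for (ci in seq_along(classes)) {
      n <- scene$n_organelles
      if (classes[ci] == "lo-cell") {
        strata <- rep("lo", n)
      } else {
        counts <- floor(props * n)
        rem <- n - sum(counts)
        if (rem > 0) {
          extra <- rep(names(props), rem)[seq_len(rem)]
          for (e in extra) counts[e] <- counts[e] + 1
        }
        strata <- sample(rep(names(counts), counts))
      }
      means <- c(lo = im$lo_mean, mid = im$mid_mean, hi = im$hi_mean)[strata]
      p <- scene
      p$seed <- NULL  # already inside the population RNG stream
      p$age_intensities <- stats::rlnorm(n, meanlog = log(means),
                                         sdlog = im$sdlog)
      cell <- make_cell_volume(p)
      cell$truth$organelles$planted_stratum <- strata[cell$truth$organelles$id]
      cell$cell_class <- classes[ci]
      cell$cell_id <- ci
      cells[[ci]] <- cell
    }
    structure(cells, class = "population")
  })
}

#' Per-organelle intensity features measured on the ground-truth masks
#'
#' Measures mean and integrated age-channel (and structural) intensity over
#' each organelle's true voxel support — the noise-limited reference used to
#' validate stratification independently of segmentation quality.
#'
#' @param population A [make_population()] result.
#' @param age_channel,structural_channel Channel names in the cell grids.
#' @return A data frame with one row per organelle: `organelle_id`,
#'   `cell_id`, `cell_class`, `planted_stratum`, `voxel_count`, and the
#'   mean/integrated intensities named after the channels (e.g.
#'   `mean_intensity_SnapTag`).
#' @export
features_from_truth <- function(population, age_channel = "SnapTag",
                                structural_channel = "Tom20") {
  stopifnot(inherits(population, "population"))
  rows <- lapply(population, function(cell) {
    org <- cell$truth$organelles
    if (nrow(org) == 0) return(NULL)
    lab <- cell$truth$label_map$labels
    age <- get_channel(cell$grid, age_channel)
    str <- get_channel(cell$grid, structural_channel)
    fg <- lab > 0
    idx <- lab[fg]
    sum_age <- rowsum(age[fg], idx)[, 1]
    sum_str <- rowsum(str[fg], idx)[, 1]
    cnt <- tabulate(idx, nbins = nrow(org))
    d <- data.frame(
      organelle_id = org$id,
      cell_id = cell$cell_id,
      cell_class = cell$cell_class,
      planted_stratum = if (!is.null(org$planted_stratum))
        org$planted_stratum else NA_character_,
      voxel_count = cnt[org$id],
      row.names = NULL)
    d[[paste0("mean_intensity_", age_channel)]] <-
      unname(sum_age[as.character(org$id)]) / cnt[org$id]
    d[[paste0("integrated_density_", age_channel)]] <-
      unname(sum_age[as.character(org$id)])
    d[[paste0("mean_intensity_", structural_channel)]] <-
      unname(sum_str[as.character(org$id)]) / cnt[org$id]
    d
  })
  do.call(rbind, rows)
}
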