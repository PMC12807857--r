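#' Multi-channel 3D intensity grid
#'
#' The in-memory representation of a (possibly anisotropic) multi-channel
#' confocal stack: a 4D array indexed `(z, y, x, channel)` together with the
#' per-axis physical voxel spacing in micrometres and unique channel names.
#'
#' @param data Numeric array, either 3D `(z, y, x)` for a single channel or
#'   4D `(z, y, x, channel)`. All intensities must be nonnegative.
#' @param spacing_um Numeric length-3 vector of voxel spacings in µm, in
#'   axis order `(z, y, x)`. All entries must be strictly positive.
#' @param channel_names Character vector of unique channel names, one per
#'   channel. Defaults to `"ch1"`, `"ch2"`, ...
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 8, 8)), spacing_um = c(0.13, 0.043, 0.043))
#' dim(g$data)
#' @export
voxel_grid <- function(data, spacing_um, channel_names = NULL) {
  if (length(dim(data)) == 3) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4) {
    stop("`data` must be a 3D (z, y, x) or 4D (z, y, x, channel) array")
  }
  if (any(data < 0, na.rm = TRUE)) stop("intensities must be nonnegative")
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3 || any(!is.finite(spacing_um)) ||
      any(spacing_um <= 0)) {
    stop("`spacing_um` must be 3 positive values (z, y, x)")
  }
  nc <- dim(data)[4]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nc || anyDuplicated(channel_names)) {
    stop("`channel_names` must be unique, one per channel")
  }
  structure(
    list(data = data, spacing_um = stats::setNames(spacing_um, c("z", "y", "x")),
         channel_names = channel_names),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels (z,y,x), %d channel(s): %s\n",
              d[1], d[2], d[3], d[4], paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  spacing (um): z=%.4g y=%.4g x=%.4g\n",
              x$spacing_um[1], x$spacing_um[2], x$spacing_um[3]))
  invisible(x)
}

#' Extract one channel of a grid as a 3D array
#'
#' @param grid A [voxel_grid()].
#' @param channel Channel name or index.
#' @return A 3D numeric array `(z, y, x)`.
#' @export
get_channel <- function(grid, channel) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.character(channel)) {
    i <- match(channel, grid$channel_names)
    if (is.na(i)) {
      stop(sprintf("unknown channel '%s' (available: %s)", channel,
                   paste(grid$channel_names, collapse = ", ")))
    }
    channel <- i
  }
  grid$data[, , , channel, drop = TRUE]
}

#' Labelled organelle volume
#'
#' Integer-labelled 3D volume in which each positive id marks one connected
#' organelle and 0 is background. Carries the connectivity used for
#' labelling, the voxel spacing of its source grid, and a provenance list of
#' every processing stage (with parameters) that produced it.
#'
#' @param labels Integer 3D array `(z, y, x)`, nonnegative.
#' @param spacing_um Voxel spacing of the source grid (z, y, x), µm.
#' @param connectivity 6 or 26.
#' @param provenance List of stage records (name + parameters).
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, spacing_um, connectivity = 26L,
                      provenance = list()) {
  stopifnot(length(dim(labels)) == 3, all(labels >= 0),
            connectivity %in% c(6L, 26L))
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels,
         spacing_um = stats::setNames(as.numeric(spacing_um), c("z", "y", "x")),
         connectivity = as.integer(connectivity),
         provenance = provenance),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  ids <- setdiff(unique(as.integer(x$labels)), 0L)
  cat(sprintf("<label_map> %s voxels, %d organelle(s), connectivity %d\n",
              paste(dim(x$labels), collapse = " x "), length(ids),
              x$connectivity))
  cat(sprintf("  stages: %s\n",
              paste(vapply(x$provenance, function(s) s$stage, ""),
                    collapse = " -> ")))
  invisible(x)
}

add_provenance <- function(lmap, stage, params) {
  lmap$provenance <- c(lmap$provenance, list(c(list(stage = stage), params)))
  lmap
}

#' Ids of the organelles present in a label map
#'
#' @param lmap A [label_map()].
#' @return Sorted integer vector of the positive label ids with at least
#'   one voxel (ids need not be contiguous after filtering).
#' @export
label_ids <- function(lmap) {
  m <- max(lmap$labels)
  if (m == 0) return(integer(0))
  sizes <- .cpp_label_sizes(lmap$labels, m)
  which(sizes > 0)
}

#' Read a multi-channel stack from TIFF
#'
#' Stacks are stored as multi-page 32-bit float TIFF (pages ordered z within
#' channel) with a JSON sidecar (`<path>.json`) holding the voxel spacing,
#' channel names, array shape and intensity scale. Spacing and channel names
#' from the sidecar can be overridden; without a sidecar they must be given.
#'
#' @param path TIFF file path.
#' @param spacing_um Optional spacing override (z, y, x), µm.
#' @param channel_names Optional channel-name override.
#' @return A [voxel_grid()].
#' @export
read_stack <- function(path, spacing_um = NULL, channel_names = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else NULL
  if (is.null(spacing_um)) {
    if (is.null(meta$spacing_um)) {
      stop("no spacing metadata found; supply `spacing_um`")
    }
    spacing_um <- meta$spacing_um
  }
  if (is.null(channel_names)) channel_names <- meta$channel_names
  nz <- if (!is.null(meta$shape)) meta$shape[1] else length(pages)
  nc <- if (!is.null(meta$shape)) meta$shape[4] else 1L
  if (nz * nc != length(pages)) stop("page count does not match metadata shape")
  if (nz < 2) stop("stack has fewer than 2 z-planes; 2D images are not supported")
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  arr <- array(0, c(nz, ny, nx, nc))
  for (ci in seq_len(nc)) {
    for (zi in seq_len(nz)) {
      arr[zi, , , ci] <- pages[[(ci - 1L) * nz + zi]] * scale
    }
  }
  voxel_grid(arr, spacing_um = spacing_um, channel_names = channel_names)
}

#' Write a grid as a multi-page float TIFF plus JSON sidecar
#'
#' @param grid A [voxel_grid()].
#' @param path Output TIFF path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$data)
  scale <- max(grid$data)
  if (scale <= 0) scale <- 1
  pages <- vector("list", d[1] * d[4])
  for (ci in seq_len(d[4])) {
    for (zi in seq_len(d[1])) {
      pages[[(ci - 1L) * d[1] + zi]] <-
        matrix(grid$data[zi, , , ci] / scale, d[2], d[3])
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(shape = d, spacing_um = unname(grid$spacing_um),
               channel_names = grid$channel_names, intensity_scale = scale,
               axis_order = "zyx (0-based voxel indices)")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a label map as 16-bit TIFF plus provenance JSON
#'
#' @param lmap A [label_map()].
#' @param path Output TIFF path; provenance goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(lmap, path) {
  stopifnot(inherits(lmap, "label_map"))
  m <- max(lmap$labels)
  if (m > 65535) stop("more than 65535 labels cannot be stored as 16-bit TIFF")
  d <- dim(lmap$labels)
  pages <- lapply(seq_len(d[1]), function(zi) {
    matrix(lmap$labels[zi, , ] / 65535, d[2], d[3])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  meta <- list(shape = d, spacing_um = unname(lmap$spacing_um),
               connectivity = lmap$connectivity, provenance = lmap$provenance,
               axis_order = "zyx (0-based voxel indices)")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#'
#' @param path TIFF path.
#' @return A [label_map()].
#' @export
read_label_map <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  nz <- length(pages)
  labels <- array(0L, c(nz, nrow(pages[[1]]), ncol(pages[[1]])))
  for (zi in seq_len(nz)) labels[zi, , ] <- as.integer(round(pages[[zi]] * 65535))
  prov <- meta$provenance
  label_map(labels, spacing_um = meta$spacing_um,
            connectivity = meta$connectivity,
            provenance = if (is.null(prov)) list() else prov)
}
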