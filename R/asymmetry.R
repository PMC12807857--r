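# Daughter-cell asymmetric-inheritance quantification: integrated density,
# pair orientation, the (P1 - P2)/(P1 + P2) score and its classification.

#' Integrated density of a channel over a region
#'
#' Sum of voxel intensities of the named channel over a logical mask: the
#' cargo quantity entering the asymmetry score (it reflects both the volume
#' and the fluorescence intensity of the cargo in the region).
#'
#' @param grid A [voxel_grid()].
#' @param mask Logical array matching the grid geometry.
#' @param channel Channel name or index.
#' @return A nonnegative number; 0 with a warning for an empty mask.
#' @export
integrated_density <- function(grid, mask, channel) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!identical(dim(mask), dim(grid$data)[1:3])) {
    stop("mask geometry does not match the grid")
  }
  if (!any(mask)) {
    warning("empty mask; integrated density is 0")
    return(0)
  }
  ch <- get_channel(grid, channel)
  sum(ch[mask])
}

#' Orient a daughter pair into (P1, P2)
#'
#' With a reference marker (e.g. CD8 or old-mitochondria density), P1 is
#' the cargo density of the reference-high daughter, so the score keeps its
#' sign and can be negative. Without a reference, P1 is simply the larger
#' cargo density (score >= 0; the "below -0.2" branch of the classification
#' is then unreachable). A reference tie falls back to larger-first with a
#' message.
#'
#' @param cargo_a,cargo_b Cargo integrated densities of the two daughters.
#' @param ref_a,ref_b Optional reference-channel integrated densities.
#' @return Named numeric vector `c(P1 = ..., P2 = ...)`.
#' @export
orient_pair <- function(cargo_a, cargo_b, ref_a = NULL, ref_b = NULL) {
  stopifnot(cargo_a >= 0, cargo_b >= 0)
  if (!is.null(ref_a) && !is.null(ref_b)) {
    if (ref_a == ref_b) {
      message("reference tie; falling back to larger-first orientation")
    } else if (ref_a > ref_b) {
      return(c(P1 = cargo_a, P2 = cargo_b))
    } else {
      return(c(P1 = cargo_b, P2 = cargo_a))
    }
  }
  c(P1 = max(cargo_a, cargo_b), P2 = min(cargo_a, cargo_b))
}

#' Asymmetric-inheritance score
#'
#' `s = (P1 - P2) / (P1 + P2)` on the oriented daughter integrated
#' densities. The score is antisymmetric (swapping P1 and P2 negates it),
#' scale-invariant, and `s = 0.2` corresponds exactly to a 1.5-fold
#' inheritance ratio `P1/P2 = 1.5`.
#'
#' @param P1,P2 Nonnegative integrated densities (vectorized).
#' @return The score in \[-1, 1\], or `NA` for a degenerate pair
#'   (`P1 + P2 = 0`).
#' @examples
#' asymmetry_score(1.5, 1.0)  # 0.2, the classification boundary
#' @export
asymmetry_score <- function(P1, P2) {
  stopifnot(all(P1 >= 0, na.rm = TRUE), all(P2 >= 0, na.rm = TRUE))
  tot <- P1 + P2
  ifelse(tot > 0, (P1 - P2) / tot, NA_real_)
}

#' Classify a pair as asymmetric or symmetric
#'
#' A division is asymmetric when the score is strictly above `threshold`
#' or strictly below `-threshold` (default 0.2, i.e. one daughter inherits
#' at least 1.5x more cargo than its sibling); boundary values are
#' symmetric. `NA` scores are degenerate.
#'
#' @param s Score(s) from [asymmetry_score()].
#' @param threshold Classification threshold (default 0.2).
#' @return Character vector: `"asymmetric"`, `"symmetric"` or
#'   `"degenerate"`.
#' @export
classify_pair <- function(s, threshold = 0.2) {
  stopifnot(threshold >= 0)
  out <- ifelse(is.na(s), "degenerate",
                ifelse(s > threshold | s < -threshold, "asymmetric",
                       "symmetric"))
  out
}

#' Measure one daughter pair on a stack
#'
#' Computes the oriented integrated densities, the asymmetry score and the
#' classification for one mitotic pair given its two daughter masks.
#'
#' @param grid A [voxel_grid()].
#' @param mask1,mask2 Disjoint logical daughter masks.
#' @param cargo_channel Channel whose inheritance is quantified.
#' @param reference_channel Optional orientation channel (e.g. a CD8-like
#'   marker); `NULL` uses larger-first orientation.
#' @param threshold Classification threshold.
#' @param pair_id Identifier carried into the output row.
#' @param group Optional group label.
#' @return One-row data frame: `pair_id`, `group`, `P1`, `P2`, `score`,
#'   `classification`.
#' @export
measure_pair <- function(grid, mask1, mask2, cargo_channel,
                         reference_channel = NULL, threshold = 0.2,
                         pair_id = 1L, group = NA_character_) {
  if (any(mask1 & mask2)) stop("daughter masks must be disjoint")
  Pa <- integrated_density(grid, mask1, cargo_channel)
  Pb <- integrated_density(grid, mask2, cargo_channel)
  if (!is.null(reference_channel)) {
    ra <- integrated_density(grid, mask1, reference_channel)
    rb <- integrated_density(grid, mask2, reference_channel)
    p <- orient_pair(Pa, Pb, ra, rb)
  } else {
    p <- orient_pair(Pa, Pb)
  }
  s <- asymmetry_score(p["P1"], p["P2"])
  data.frame(pair_id = pair_id, group = group, P1 = unname(p["P1"]),
             P2 = unname(p["P2"]), score = unname(s),
             classification = classify_pair(unname(s), threshold))
}

#' Summarize measured pairs per group
#'
#' Per-group count, asymmetric fraction (among non-degenerate pairs), mean
#' score, standard deviation and standard error; degenerate pairs are
#' counted separately and excluded from the statistics.
#'
#' @param pairs Data frame of [measure_pair()] rows (columns `score`,
#'   `classification` and `group`).
#' @param group_col Grouping column name.
#' @return A data frame with one row per group.
#' @export
pair_report <- function(pairs, group_col = "group") {
  stopifnot(is.data.frame(pairs), "score" %in% names(pairs),
            "classification" %in% names(pairs))
  if (all(pairs$classification == "degenerate")) {
    stop("all pairs are degenerate; nothing to summarize")
  }
  g <- if (group_col %in% names(pairs)) as.character(pairs[[group_col]]) else
    rep(NA_character_, nrow(pairs))
  g[is.na(g)] <- "all"
  out <- lapply(split(pairs, g), function(d) {
    ok <- d$classification != "degenerate"
    s <- d$score[ok]
    data.frame(
      group = g[match(rownames(d)[1], rownames(pairs))][1],
      n_pairs = nrow(d),
      n_degenerate = sum(!ok),
      fraction_asymmetric = mean(d$classification[ok] == "asymmetric"),
      mean_score = mean(s),
      sd_score = stats::sd(s),
      sem_score = stats::sd(s) / sqrt(sum(ok)))
  })
  out <- do.call(rbind, out)
  out$group <- names(split(pairs, g))
  rownames(out) <- NULL
  out
}
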