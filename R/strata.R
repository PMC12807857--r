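# Age-label intensity stratification of organelles into lo/mid/hi strata.

#' Compute the lo/mid/hi stratification thresholds
#'
#' The two-threshold rule uses the organelles of the current dataset as
#' reference populations: `t_lo` is the maximum mean age-label intensity
#' among organelles of lo-class cells, and `t_hi` is the 75th percentile
#' (linear interpolation between order statistics) of mean age-label
#' intensity among organelles of hi-class cells.
#'
#' @param features Data frame with one row per organelle carrying the cell
#'   class and mean age-label intensity.
#' @param intensity_col Name of the mean age-label intensity column.
#' @param class_col Name of the cell-class column (values `"lo-cell"` /
#'   `"hi-cell"`).
#' @return An object of class `intensity_strata`: `t_lo`, `t_hi`,
#'   `n_reference_lo`, `n_reference_hi`, `percentile_method`. If
#'   `t_hi < t_lo` the mid stratum is empty; this is allowed and messaged.
#' @examples
#' f <- data.frame(
#'   cell_class = rep(c("lo-cell", "hi-cell"), c(3, 4)),
#'   mean_intensity_SnapTag = c(10, 20, 100, 50, 150, 250, 350))
#' s <- compute_strata_thresholds(f)
#' c(s$t_lo, s$t_hi)  # 100, 275
#' @export
compute_strata_thresholds <- function(features,
                                      intensity_col = "mean_intensity_SnapTag",
                                      class_col = "cell_class") {
  stopifnot(is.data.frame(features),
            intensity_col %in% names(features),
            class_col %in% names(features))
  cls <- features[[class_col]]
  lo <- features[[intensity_col]][cls == "lo-cell"]
  hi <- features[[intensity_col]][cls == "hi-cell"]
  if (length(lo) == 0) stop("no organelles of class 'lo-cell' in `features`")
  if (length(hi) == 0) stop("no organelles of class 'hi-cell' in `features`")
  t_lo <- max(lo)
  t_hi <- percentile(hi, 75)
  if (t_hi < t_lo) {
    message("t_hi < t_lo: the mid stratum is empty for this dataset")
  }
  structure(
    list(t_lo = t_lo, t_hi = t_hi,
         n_reference_lo = length(lo), n_reference_hi = length(hi),
         percentile_method = "linear interpolation between order statistics"),
    class = "intensity_strata")
}

#' @export
print.intensity_strata <- function(x, ...) {
  cat(sprintf(paste0("<intensity_strata> t_lo = %.4g (max of %d lo-cell ",
                     "organelles), t_hi = %.4g (75th pct of %d hi-cell ",
                     "organelles)\n"),
              x$t_lo, x$n_reference_lo, x$t_hi, x$n_reference_hi))
  invisible(x)
}

#' Assign lo/mid/hi strata to organelles
#'
#' Organelles of lo-class cells are stratum `"lo"` unconditionally. For
#' hi-class cells: intensity `<= t_lo` is `"lo"`, intensity in
#' `(t_lo, t_hi]` is `"mid"`, and intensity strictly above `t_hi` is
#' `"hi"`. Assignments are invariant to rescaling all intensities by a
#' common positive factor only if the thresholds are recomputed on the
#' rescaled data.
#'
#' @param features Data frame as in [compute_strata_thresholds()].
#' @param strata An `intensity_strata` object.
#' @param intensity_col,class_col Column names.
#' @return `features` with an added `stratum` column.
#' @export
assign_strata <- function(features, strata,
                          intensity_col = "mean_intensity_SnapTag",
                          class_col = "cell_class") {
  stopifnot(inherits(strata, "intensity_strata"),
            intensity_col %in% names(features),
            class_col %in% names(features))
  v <- features[[intensity_col]]
  cls <- features[[class_col]]
  stratum <- ifelse(v > strata$t_hi, "hi",
                    ifelse(v > strata$t_lo, "mid", "lo"))
  stratum[cls == "lo-cell"] <- "lo"
  features$stratum <- stratum
  features
}
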