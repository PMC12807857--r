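# Group statistics used on morphometry and pair data: Welch's unequal-
# variance t-test, the Kruskal-Wallis/Dunn pairwise post hoc test with
# Bonferroni correction, and the linear-interpolation percentile.

#' Welch's unequal-variance t-test
#'
#' Two-sample t statistic `t = (mean(x) - mean(y)) / sqrt(sx^2/nx + sy^2/ny)`
#' with Welch–Satterthwaite degrees of freedom and (by default) a two-sided
#' p-value. When both samples have zero variance the test degenerates:
#' equal means give `p = 1`, unequal means give `p = 0` (flagged in the
#' `note` column).
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param comparison Label carried into the result.
#' @return One-row data frame: `comparison`, `statistic`, `df`, `p_value`,
#'   `note`.
#' @export
welch_t_test <- function(x, y, alternative = c("two.sided", "less", "greater"),
                         comparison = "x vs y") {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least 2 finite observations")
  }
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  note <- NA_character_
  if (se2 == 0) {
    if (mean(x) == mean(y)) {
      t <- 0; df <- nx + ny - 2; p <- 1
      note <- "zero variance, equal means"
    } else {
      t <- sign(mean(x) - mean(y)) * Inf; df <- nx + ny - 2; p <- 0
      note <- "zero variance, unequal means"
    }
  } else {
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    p <- switch(alternative,
                two.sided = 2 * stats::pt(-abs(t), df),
                less = stats::pt(t, df),
                greater = stats::pt(t, df, lower.tail = FALSE))
  }
  data.frame(comparison = comparison, statistic = t, df = df, p_value = p,
             note = note)
}

#' Dunn's pairwise post hoc test with Bonferroni correction
#'
#' Nonparametric all-pairwise comparison on the joint midranks of all
#' groups (the post hoc companion of the Kruskal-Wallis test):
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))` with
#' the tie correction `T = sum(t^3 - t) / (12 (N - 1))`, two-sided normal
#' p-values and Bonferroni adjustment `p_adj = min(1, p * k)` over the `k`
#' pairwise comparisons actually performed. With completely tied data the
#' variance degenerates and `p = 1` is reported.
#'
#' @param values Numeric vector of observations, or a list of numeric
#'   group samples (then `groups` is ignored).
#' @param groups Group labels parallel to `values`.
#' @return A data frame with one row per pair: `comparison`, `statistic`
#'   (z), `p_value`, `adjusted_p`, plus attributes `kruskal_p` from the
#'   companion Kruskal-Wallis test.
#' @export
dunn_test <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(names(values) %||% seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) {
    stop("every group needs at least 2 observations: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  N <- length(values)
  r <- rank(values)  # midranks for ties
  rbar <- tapply(r, groups, mean)
  n <- as.numeric(tab)[match(names(rbar), names(tab))]
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  gn <- names(rbar)
  pairs <- utils::combn(length(gn), 2)
  k <- ncol(pairs)
  rows <- lapply(seq_len(k), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    v <- var_base * (1 / n[i1] + 1 / n[i2])
    if (v <= 0) {
      z <- 0; p <- 1
    } else {
      z <- (rbar[i1] - rbar[i2]) / sqrt(v)
      p <- 2 * stats::pnorm(-abs(z))
    }
    data.frame(comparison = paste(gn[i1], "vs", gn[i2]),
               statistic = unname(z), p_value = unname(p),
               adjusted_p = min(1, unname(p) * k))
  })
  out <- do.call(rbind, rows)
  kw <- tryCatch(stats::kruskal.test(values, factor(groups))$p.value,
                 error = function(e) NA_real_)
  attr(out, "kruskal_p") <- kw
  attr(out, "n_comparisons") <- k
  out
}

#' Percentile with linear interpolation between order statistics
#'
#' The convention used by the age-stratification rule (and the common
#' default in scientific software): the q-th percentile interpolates
#' linearly between the two closest order statistics.
#'
#' @param values Nonempty numeric vector.
#' @param q Percentile(s) in \[0, 100\].
#' @return The interpolated percentile value(s).
#' @examples
#' percentile(c(50, 150, 250, 350), 75)  # 275
#' @export
percentile <- function(values, q) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("`values` must be nonempty")
  stopifnot(all(q >= 0 & q <= 100))
  unname(stats::quantile(values, probs = q / 100, type = 7))
}
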