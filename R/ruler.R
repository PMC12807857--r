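# Histone proteomic-ruler copy numbers and the differential-inheritance
# filter applied to protein quantification tables.

#' Proteomic-ruler constants
#'
#' The ruler calibrates mass-spectrometric intensities against the histone
#' signal, exploiting the fixed histone:DNA mass relationship of a cell:
#' the DNA mass per cell is `m_DNA = genome_size_bp * ploidy *
#' mean_bp_molar_mass / N_A` grams, and total histone mass per cell is
#' taken equal to `m_DNA`.
#'
#' @param genome_size_bp Haploid genome size in base pairs (default: mouse,
#'   2.7e9).
#' @param ploidy Genome copies per cell (default 2; proliferating cultures
#'   average higher).
#' @param mean_bp_molar_mass Mean molar mass of one base pair, g/mol
#'   (default 615.8771, the standard value with one water removed per
#'   phosphodiester bond).
#' @param avogadro Avogadro's number.
#' @return A list of class `ruler_config`.
#' @export
ruler_config <- function(genome_size_bp = 2.7e9, ploidy = 2,
                         mean_bp_molar_mass = 615.8771,
                         avogadro = 6.02214076e23) {
  stop_if_not_positive(genome_size_bp, "genome_size_bp")
  stop_if_not_positive(ploidy, "ploidy")
  stop_if_not_positive(mean_bp_molar_mass, "mean_bp_molar_mass")
  stop_if_not_positive(avogadro, "avogadro")
  structure(as.list(environment()), class = "ruler_config")
}

#' Per-cell protein copy numbers via the histone proteomic ruler
#'
#' For each sample, copy numbers are
#' `copies_i = (I_i / sum(I_histone)) * m_DNA * N_A / M_i`,
#' where `I_i` is the (mass-proportional) MS intensity, `M_i` the molar
#' mass and `m_DNA` the DNA mass per cell from [ruler_config()]. Copy
#' numbers are invariant to global per-sample intensity rescaling and the
#' summed histone mass per cell equals `m_DNA` by construction.
#'
#' @param quant Data frame with columns `protein_id`, `is_histone`
#'   (logical), `molar_mass` (g/mol) and one intensity column per sample.
#' @param sample_cols Names of the sample intensity columns; defaults to
#'   all numeric columns except `molar_mass`.
#' @param config A [ruler_config()].
#' @return A list of class `protein_copy_numbers`: `copies` (protein x
#'   sample matrix), `mass_fraction` (per-sample protein mass fractions),
#'   `m_dna_g`, `uncomputable` (samples with no histone signal, whose
#'   columns are `NA`), and the input `quant`.
#' @export
copy_numbers <- function(quant, sample_cols = NULL, config = ruler_config()) {
  stopifnot(is.data.frame(quant),
            all(c("protein_id", "is_histone", "molar_mass") %in% names(quant)),
            inherits(config, "ruler_config"))
  stop_if_not_positive(quant$molar_mass, "molar_mass")
  if (is.null(sample_cols)) {
    sample_cols <- setdiff(names(quant)[vapply(quant, is.numeric, TRUE)],
                           "molar_mass")
  }
  stopifnot(length(sample_cols) >= 1)
  I <- as.matrix(quant[, sample_cols, drop = FALSE])
  if (any(I < 0, na.rm = TRUE)) stop("intensities must be nonnegative")
  m_dna <- config$genome_size_bp * config$ploidy *
    config$mean_bp_molar_mass / config$avogadro
  hist_sum <- colSums(I[quant$is_histone, , drop = FALSE], na.rm = TRUE)
  uncomputable <- sample_cols[hist_sum <= 0]
  if (length(uncomputable) > 0) {
    warning("no histone signal in sample(s): ",
            paste(uncomputable, collapse = ", "),
            "; copy numbers set to NA there")
  }
  copies <- sweep(I, 2, hist_sum, "/") * m_dna * config$avogadro /
    quant$molar_mass
  copies[, hist_sum <= 0] <- NA_real_
  total <- colSums(I, na.rm = TRUE)
  mass_fraction <- sweep(I, 2, ifelse(total > 0, total, NA_real_), "/")
  rownames(copies) <- rownames(mass_fraction) <- quant$protein_id
  structure(
    list(copies = copies, mass_fraction = mass_fraction, m_dna_g = m_dna,
         uncomputable = uncomputable, quant = quant,
         sample_cols = sample_cols, config = config),
    class = "protein_copy_numbers")
}

#' @export
print.protein_copy_numbers <- function(x, ...) {
  cat(sprintf("<protein_copy_numbers> %d proteins x %d samples; m_DNA = %.3g pg\n",
              nrow(x$copies), ncol(x$copies), x$m_dna_g * 1e12))
  invisible(x)
}

#' Differential-inheritance filter between two sample groups
#'
#' Per protein: the fold change is the ratio of group geometric means
#' (group A over group B) and the p-value comes from Welch's unequal-
#' variance t-test on log2-transformed values. A protein is significant
#' when `p < 0.05` and the fold change passes the gate
#' `FC > fc_upper` or `FC < fc_lower` (defaults 1.5 and 1/1.5; the exact
#' reciprocal is used so the filter is symmetric under swapping the
#' groups — 1/1.5 = 0.667 rather than the rounded 0.67). Zero or missing
#' intensities are excluded per protein rather than imputed; proteins
#' quantified in fewer than 2 samples of either group are reported as
#' not testable (mirroring categorical presence/absence reporting).
#'
#' @param cn A [copy_numbers()] result, or a protein x sample numeric
#'   matrix with row names.
#' @param group_a,group_b Character vectors of sample (column) names.
#' @param p_cutoff Significance threshold on the Welch p-value.
#' @param fc_upper,fc_lower Fold-change gates.
#' @return A data frame with one row per protein: `protein_id`, `n_a`,
#'   `n_b`, `log2_fc`, `fold_change`, `p_value`, `testable`,
#'   `significant`.
#' @export
differential_inheritance <- function(cn, group_a, group_b, p_cutoff = 0.05,
                                     fc_upper = 1.5, fc_lower = 1 / 1.5) {
  m <- if (inherits(cn, "protein_copy_numbers")) cn$copies else as.matrix(cn)
  stopifnot(all(group_a %in% colnames(m)), all(group_b %in% colnames(m)),
            length(group_a) >= 2, length(group_b) >= 2)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    a <- m[i, group_a]; b <- m[i, group_b]
    a <- a[is.finite(a) & a > 0]; b <- b[is.finite(b) & b > 0]
    la <- log2(a); lb <- log2(b)
    testable <- length(a) >= 2 && length(b) >= 2
    if (testable) {
      fc <- 2^(mean(la) - mean(lb))
      p <- welch_t_test(la, lb)$p_value
      sig <- p < p_cutoff && (fc > fc_upper || fc < fc_lower)
    } else {
      fc <- if (length(a) >= 1 && length(b) >= 1) {
        2^(mean(la) - mean(lb))
      } else NA_real_
      p <- NA_real_
      sig <- FALSE
    }
    data.frame(protein_id = rownames(m)[i], n_a = length(a), n_b = length(b),
               log2_fc = log2(fc), fold_change = fc, p_value = p,
               testable = testable, significant = sig)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a protein quantification table with planted group differences
#'
#' Generates a mass-spectrometry-style protein x sample intensity table
#' with a histone subset (calibrating the proteomic ruler), log-normal
#' biological and technical spread, per-sample global intensity scale
#' factors, and a planted fold change on a chosen set of proteins.
#'
#' @param n_proteins Total number of proteins (including histones).
#' @param n_histones Number of histone-flagged proteins.
#' @param n_per_group Samples per group (groups `A` and `B`).
#' @param n_effect Number of non-histone proteins with a planted effect.
#' @param effect_fold Planted linear fold change (group A over B);
#'   half the planted proteins go up, half down.
#' @param sd_log2 Within-group spread of log2 intensities.
#' @param seed Integer RNG seed.
#' @return A list: `quant` (the table, sample columns `A1..`, `B1..`),
#'   `truth` (data frame of planted effect proteins and directions),
#'   `group_a`, `group_b`.
#' @export
simulate_protein_table <- function(n_proteins = 300, n_histones = 8,
                                   n_per_group = 4, n_effect = 20,
                                   effect_fold = 2, sd_log2 = 0.25,
                                   seed = NULL) {
  stopifnot(n_histones >= 1, n_proteins > n_histones, n_per_group >= 2,
            n_effect >= 0, n_effect <= n_proteins - n_histones,
            effect_fold > 0)
  with_seed(seed, {
    ids <- c(sprintf("HIST%d", seq_len(n_histones)),
             sprintf("PROT%04d", seq_len(n_proteins - n_histones)))
    is_histone <- c(rep(TRUE, n_histones), rep(FALSE, n_proteins - n_histones))
    molar_mass <- stats::rlnorm(n_proteins, meanlog = log(4.5e4), sdlog = 0.5)
    molar_mass[is_histone] <- stats::runif(n_histones, 11000, 23000)
    base_copies <- stats::rlnorm(n_proteins, meanlog = log(2e5), sdlog = 1.2)
    base_copies[is_histone] <- stats::rlnorm(n_histones, meanlog = log(2e7),
                                             sdlog = 0.3)
    base_mass <- base_copies * molar_mass  # intensity is mass-proportional
    effect_idx <- if (n_effect > 0) {
      n_histones + sample.int(n_proteins - n_histones, n_effect)
    } else integer(0)
    direction <- rep_len(c(1, -1), length(effect_idx))
    groups <- rep(c("A", "B"), each = n_per_group)
    sample_names <- paste0(groups, rep(seq_len(n_per_group), 2))
    log2_effect <- matrix(0, n_proteins, length(sample_names))
    if (n_effect > 0) {
      log2_effect[effect_idx, groups == "A"] <-
        direction * log2(effect_fold) / 2
      log2_effect[effect_idx, groups == "B"] <-
        -direction * log2(effect_fold) / 2
    }
    scale_factors <- stats::rlnorm(length(sample_names), 0, 0.2)
    I <- matrix(0, n_proteins, length(sample_names),
                dimnames = list(ids, sample_names))
    for (s in seq_along(sample_names)) {
      I[, s] <- base_mass * 2^(log2_effect[, s] +
                                 stats::rnorm(n_proteins, 0, sd_log2)) *
        scale_factors[s]
    }
    quant <- data.frame(protein_id = ids, is_histone = is_histone,
                        molar_mass = molar_mass, I, check.names = FALSE)
    truth <- data.frame(protein_id = ids[effect_idx],
                        direction = ifelse(direction > 0, "up_in_A",
                                           "down_in_A"),
                        planted_fold = effect_fold^direction)
    list(quant = quant, truth = truth,
         group_a = sample_names[groups == "A"],
         group_b = sample_names[groups == "B"])
  })
}
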