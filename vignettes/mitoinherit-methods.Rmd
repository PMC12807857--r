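---
title: "Quantifying mitochondrial architecture and asymmetric inheritance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial architecture and asymmetric inheritance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoinherit)
```

## The analysis problem

When a CD8+ T cell divides, its two daughters can inherit unequal shares
of cellular cargo — in particular, mitochondria of different ages. Systems
that covalently pulse-label the outer mitochondrial membrane (a SnapTag
fused to OMP25, imaged alongside a pan-mitochondrial Tom20 stain) make
organelle age visible: organelles made before mitosis carry the "old"
label brightly, organelles made after carry little of it. Three
quantitative questions follow, and this package implements the
computational machinery for all three:

1. **Morphology** — segment individual mitochondria in 3D confocal stacks
   and measure their architecture (volume, surface area, sphericity,
   complexity, roundness, solidity).
2. **Age stratification** — split organelles into low / intermediate /
   high age-label strata with a reference-population rule.
3. **Inheritance asymmetry** — score how unequally a mitotic pair of
   daughter cells partitions a cargo, and classify the division as
   symmetric or asymmetric.

A fourth, independent module estimates per-cell protein copy numbers from
mass-spectrometric intensities with the histone proteomic ruler and
applies a significance-plus-fold-change filter to find differentially
inherited proteins.

Because real imaging and MS data are large and instrument-specific, the
package ships a synthetic-data module that generates ground-truthed
stacks, daughter pairs and protein tables with the statistical structure
the analysis assumes. Every pipeline stage is tested against that truth.

## Segmentation

The segmentation stack mirrors standard 3D confocal practice:

1. **Isotropic resampling.** Confocal stacks are anisotropic (z-steps of
   0.13 µm against ~0.043 µm in xy, a 3:1 ratio). All channels are
   upscaled to the finest spacing by trilinear interpolation with voxel
   centers aligned in physical space. Linear (order-1) interpolation is
   the default because cubic schemes can overshoot around dim organelles
   and produce negative lobes; the order is configurable.
2. **Channel fusion.** The structural and age channels are each min–max
   normalized to [0, 1] and combined voxelwise by maximum, so organelles
   visible in only one channel still segment.
3. **Outline enhancement.** A gradient-magnitude term
   `vol + alpha * |∇(G_sigma * vol)| / max` (defaults `alpha = 0.5`,
   `sigma = 0.1` µm) boosts organelle outlines before thresholding. The
   blur uses normalized convolution so constant regions stay constant at
   the volume borders. This operator is deliberately simple and fully
   recorded in provenance; both knobs are configurable.
4. **Multi-Otsu thresholding** with `k = 3` classes, foreground = top
   class. The background / halo / organelle triad is the typical
   intensity structure of a stained cell; both `k` and the number of
   foreground classes are configurable. Thresholds maximize between-class
   variance by exhaustive search over histogram bin boundaries (128 bins
   by default); ties break toward the lowest threshold set, and `k = 2`
   reduces to classical Otsu. The implementation is verified in the test
   suite against an independent brute-force search on 64-bin histograms.
5. **Morphological cleanup**, default order closing (ball radius 1) →
   3D hole filling → erosion (radius 1): close and fill first to repair
   speckle and internal holes, erode last so that organelles touching at
   a point separate. The order and radii are configurable and recorded.
6. **Connected-component labelling** at 26-connectivity (6 available).
7. **Size filter**: components strictly smaller than 500 voxels are
   treated as noise and removed; a component of exactly 500 voxels is
   kept. The filter runs on the isotropic grid, after upscaling.

Every `label_map` carries a provenance list naming each stage and its
parameters, so any segmentation is reproducible from its output alone.

## Morphometry

For each organelle with volume `V` (voxel count × voxel volume) and
surface area `SA`:

- **Sphericity** `ψ = π^(1/3) (6V)^(2/3) / SA`, 1 for a perfect sphere.
- **Complexity index** `MCI = SA³ / (36 π V²) = 1/ψ³`, 1 for a sphere and
  increasing for elongated or branched organelles. With this normalizer
  the identity `MCI · ψ³ = 1` holds exactly on every record (asserted in
  the tests), and both quantities are invariant to uniform rescaling of
  the voxel spacing.
- **Roundness** = equivalent-sphere diameter over the major
  principal-axis length `2·sqrt(5 λ₁)`, with `λ₁` the leading eigenvalue
  of the voxel-cloud covariance (plus the voxel's own second moment
  `spacing²/12`, which regularizes single-voxel objects).
- **Compactness** (solidity) = voxel count over the voxel count of the
  rasterized convex hull of the organelle's voxel centers — the
  convention of standard region-property implementations, ≈1 for convex
  shapes, low for bent or branched ones.
- **Intensities**: per-channel mean (sum / voxel count) and integrated
  density measured on the raw resampled channels over the label support,
  never on the outline-enhanced volume. Background subtraction is off by
  default.

There is no universal 3D definition of roundness or compactness; the two
chosen here give high values to tight, unbranched organelles and are
documented in the function reference so downstream users know exactly
what was computed.

**Surface area** comes from a marching-tetrahedra mesh of the binary
mask at iso-level 0.5. Meshing a raw binary mask overestimates the area
of a digitized sphere by roughly 9% (the staircase bias), so the mask is
first smoothed with a small Gaussian (σ = 0.6 voxel); with that choice a
digitized sphere of radius 10 voxels meshes to within ~3.5% of `4πr²`,
`ψ ≈ 0.96` and `MCI ≈ 1.1`. Objects too small to survive smoothing
(e.g. a single voxel) are meshed unsmoothed so the area is always
positive and finite. Surface areas require an isotropic grid.

**Standardization and embedding.** Only geometric features are
standardized (column-wise z-scores) for embedding, which removes
intensity bias from the architecture analysis; zero-variance columns are
dropped with a message and the scaling is returned for reuse on held-out
data. The 2D embedding used for density maps is principal components
with a fixed sign convention: a deterministic linear embedding keeps
coordinates bit-reproducible across runs and machines, which we value
over the local-structure emphasis of nonlinear methods because the
embedding is visualization-only — no quantitative claim in the package
depends on it. A product-Gaussian kernel density estimate (bandwidth:
Scott's rule `sd · n^(-1/6)` per axis) renders the density maps; the
discrete density integrates to 1 over its grid within 1%.

## Age-label stratification

The stratification rule is deliberately simple and reference-based, not
model-based (no mixture fitting): with organelles from labelled
`lo`-class and `hi`-class cells,

- `t_lo` = maximum mean age-label intensity among organelles of lo-class
  cells;
- `t_hi` = 75th percentile of mean age-label intensity among organelles
  of hi-class cells (linear interpolation between order statistics — the
  common software default; the convention is recorded in the output);
- lo-cell organelles are stratum `lo` unconditionally; hi-cell
  organelles are `lo` if intensity ≤ `t_lo`, `mid` if in `(t_lo, t_hi]`,
  and `hi` strictly above `t_hi`.

Boundary conventions follow the rule's wording — "below the maximum"
reads as ≤ `t_lo`, "above the 75th percentile" as strictly >. The 75th
percentile is computed over *all* hi-cell organelles, not only those
above `t_lo`; with the threshold that rule produces, the alternative
reading would only shift `t_hi` upward within the same reference set,
and the choice is recorded here so it can be revisited. If `t_hi < t_lo`
the mid stratum is empty; this is legal and messaged. Reference
populations are the organelles of the current dataset, but a saved
`intensity_strata` object can be re-applied to new data for
cross-experiment comparability.

## Inheritance asymmetry

For a mitotic pair, each daughter's cargo is summarized by its
integrated density (sum of voxel intensities over the daughter mask, so
volume and intensity both count). With oriented densities `P1` and `P2`:

```
s = (P1 − P2) / (P1 + P2),   |s| > 0.2  ⇔  asymmetric
```

`s = 0.2` corresponds exactly to a 1.5-fold inheritance ratio, the
boundary itself is classified symmetric (strict inequality), and the
score is antisymmetric and scale-invariant. Orientation matters: with a
reference marker (a CD8-like channel, or the old-mitochondria density),
`P1` is the cargo of the reference-high daughter and the score keeps its
sign; without one, `P1` is simply the larger value, the score is
nonnegative, and the negative branch of the classification is
unreachable. Both modes are exposed because different cargoes anchor the
orientation differently. Degenerate pairs (`P1 + P2 = 0`) carry no score
and are reported separately.

Daughter masks are supplied by the caller (from synthetic truth or
imported annotation); detecting mitotic pairs from nuclear or tubulin
morphology is a manual step upstream of this package.

## Group statistics

- **Welch's t-test** (unequal variances, Welch–Satterthwaite degrees of
  freedom, two-sided by default) — used on log2 protein quantities.
  Degenerate zero-variance inputs return `p = 1` (equal means) or
  `p = 0` with a note (unequal means).
- **Dunn's pairwise test** on joint midranks with the tie-corrected
  variance and Bonferroni adjustment `min(1, k·p)` over the `k`
  comparisons actually performed — the post hoc companion of
  Kruskal–Wallis for comparing a feature across the lo/mid/hi strata.
  Completely tied data degenerate to `p = 1`.
- **Percentile** with linear interpolation, the convention the
  stratification rule requires.

One- and two-way ANOVA with Tukey correction, used for routine
comparisons elsewhere, are standard `stats`/`multcomp` territory and are
not re-implemented here.

## Proteomic ruler and differential inheritance

MS intensity is treated as proportional to protein mass. With the DNA
mass per cell `m_DNA = genome_size × ploidy × m_bp / N_A` (defaults:
mouse haploid 2.7 Gbp, ploidy 2, 615.8771 g/mol per bp), copy numbers
are

```
copies_i = (I_i / Σ I_histone) · m_DNA · N_A / M_i
```

so summed histone mass per cell equals `m_DNA` by construction, and copy
numbers are invariant to any global per-sample intensity scale. Which
proteins count as histones is a caller-supplied flag (an id list), not a
sequence analysis. Samples without histone signal are flagged
uncomputable rather than guessed.

The differential filter takes the fold change as the ratio of group
geometric means (log2 transform; zeros excluded per protein, never
imputed) and the p-value from Welch's test on the log2 values; a protein
is differentially inherited when `p < 0.05` and `FC > 1.5` or
`FC < 1/1.5`. The lower gate is the exact reciprocal rather than the
rounded 0.67 so the filter is symmetric under swapping the groups; the
gate is a parameter for anyone preferring the rounded convention.
Proteins quantified in fewer than two samples of either group are
reported categorically as not testable, mirroring presence/absence
reporting.

## What the synthetic module emulates — and what it does not

`make_cell_volume()` places non-overlapping organelles — capsules
(cylinders with hemispherical caps) for tubules, spheres for puncta —
inside an ellipsoidal cell flattened in z, renders photon rates through
a separable Gaussian PSF, and applies Poisson photon noise plus Gaussian
read noise. Defaults emulate the acquisition geometry the pipeline
targets: 0.13 µm z-steps with 3:1 anisotropy (xy ≈ 0.043 µm), a cell of
~5.5 µm, organelle radii ~0.45 µm, a bright/dim two-component age-label
mixture (80 vs 15 photons per voxel against background 2, read noise
1.5), and a PSF of σ = 0.2/0.08/0.08 µm (z/y/x). The noise-free truth
(label map and per-organelle records) is kept alongside.

`make_daughter_pair()` builds two disjoint ellipsoidal daughter masks
separated by a thin bridge region excluded from both, and spreads the
cargo over puncta whose daughter-2 positions mirror daughter 1's through
the division plane. The mirroring makes PSF losses cancel, so the
noise-free measured score equals `2f − 1` exactly for partition fraction
`f` — which is what lets the tests assert exact score algebra rather
than approximate recovery.

`make_population()` plants age-label strata: lo-class cells contain only
dim organelles; hi-class cells mix lo/mid/hi components in fixed 25/50/25
proportions with log-normal spread. The 25% high fraction aligns the
planted partition with the 75th-percentile threshold, so recovery
against truth is a meaningful end-to-end check of the rule.

Deliberately not simulated: Airyscan optics, photobleaching, drift, dye
dilution, autofluorescence, organelle contact or overlap, and cell-cycle
morphology. Passing tests therefore demonstrate correctness of the
computations under a clean forward model — they do not certify
segmentation accuracy on real Airyscan data, where PSF mismatch and
clutter can only degrade IoU. The regression thresholds (mean
per-organelle IoU ≥ 0.7, component recall ≥ 0.9 at SNR ≥ 5, fixed
seeds) are chosen to catch algorithmic regressions, not to claim
instrument-level performance.

## Numerical choices and problem sizes

- Mesh smoothing σ = 0.6 voxel, iso-level 0.5, with a binary fallback
  for tiny objects (above).
- Histogram resolution 128 bins for thresholding; exhaustive search is
  exact at this resolution and costs well under a second for `k ≤ 3`.
- Strict `<` in the 500-voxel filter; strict `>` at the ±0.2
  classification boundary; `≤ t_lo` / `> t_hi` in stratification.
- Convex hulls use an incremental construction with an epsilon of
  1e-9 × object diameter; solidity is clamped to [0, 1].
- Label maps store up to 65,535 organelles (16-bit TIFF), asserted at
  write time.
- The test suite and the reproduction script run on scaled-down scenes
  (cells of 4–7.5 µm, 3–12 organelles, coarser 0.24/0.08 µm grids where
  segmentation accuracy is not itself under test); the full suite
  completes in about half a minute. These sizes are the package's
  fixtures of record — large enough for every property under test, small
  enough to run anywhere.

## Known limitations

- The outline-enhancement operator is a generic gradient booster; if a
  specific feathering algorithm is required for comparability with other
  software, its output should be validated against this one on shared
  stacks.
- Surface areas (and therefore ψ and MCI) carry a few percent of
  discretization bias that shrinks with organelle size; comparisons
  between conditions are unaffected, absolute values for objects under
  ~5 voxels radius should be treated cautiously.
- The stratification rule is intentionally "arbitrary" (reference-based);
  it inherits sampling noise from the lo-cell maximum, which is an
  extreme statistic. With very few reference organelles `t_lo` is
  unstable — the object records the reference counts so users can judge.
- `differential_inheritance()` assumes intensities are mass-proportional
  and comparable across samples up to a global factor; it does not model
  batch structure.
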