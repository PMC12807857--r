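# mitoinherit

Quantitative analysis of mitochondrial architecture and inheritance in
dividing cells, from multi-channel 3D fluorescence stacks and protein
quantification tables.

When a CD8+ T cell divides, its daughters can inherit unequal shares of
old versus newly made mitochondria, and that partition shapes their
fates. Measuring it takes four computations, all implemented here for R
users working with confocal stacks of age-labelled mitochondria (e.g. a
SnapTag–OMP25 pulse label imaged alongside a Tom20 stain):

- **3D per-organelle segmentation** — isotropic resampling, channel
  fusion, outline enhancement, multi-Otsu thresholding, morphological
  cleanup, connected-component labelling, and a 500-voxel noise filter,
  with full stage provenance.
- **Morphometry** — marching-tetrahedra surface area and the standard
  shape descriptors: sphericity ψ = π^⅓(6V)^⅔/SA, complexity index
  MCI = SA³/(36πV²) = 1/ψ³ (1 for a sphere, larger for elongated or
  branched organelles), roundness, solidity, plus per-channel mean and
  integrated intensities; standardized feature matrices, 2D embeddings
  and kernel density maps.
- **Age stratification** — organelles split into lo/mid/hi age-label
  strata using reference populations: t_lo = the maximum intensity in
  lo-labelled cells, t_hi = the 75th percentile in hi-labelled cells.
- **Inheritance asymmetry** — the daughter-pair score
  s = (P1 − P2)/(P1 + P2) on integrated cargo densities, with |s| > 0.2
  (equivalently, one daughter inheriting more than 1.5× the cargo of its
  sibling) classified asymmetric.

Two companions round the pipeline out: nonparametric group statistics
(Welch's unequal-variance t-test and Dunn's pairwise post hoc test with
Bonferroni correction), and histone proteomic-ruler copy numbers
(copies_i = (I_i/ΣI_histone)·m_DNA·N_A/M_i) with the differential-
inheritance filter p < 0.05 and FC > 1.5 or < 1/1.5.

No imaging or MS download is needed to use or test any of it: a
synthetic-data module generates ground-truthed stacks (tubular and
punctate organelles, two-component age-label mixture, Gaussian PSF,
Poisson + read noise), mitotic daughter pairs with a controllable
partition fraction, and protein tables with planted group differences.

## Worked example

```r
library(mitoinherit)

# a mitotic daughter pair that inherits 68% / 32% of its old mitochondria
pr   <- make_daughter_pair(f = 0.68, total_cargo = 2e5, seed = 7)
pair <- measure_pair(pr$grid, pr$mask1, pr$mask2, cargo_channel = "cargo")
pair
#>   pair_id group       P1      P2     score classification
#> 1       1  <NA> 137779.9 66264.4 0.3504901     asymmetric
```

The measured score 0.35 sits close to the noise-free value
2f − 1 = 0.36, and exceeds the 0.2 threshold, so the division is called
asymmetric.

```r
# a synthetic cell: segment it and measure every mitochondrion
sc  <- make_cell_volume(scene_params(seed = 42))
seg <- segment_stack(sc$grid)
feats <- compute_features(seg$label_map, seg$grid_iso, cell_class = "hi-cell")
nrow(feats)   # all 10 planted organelles recovered
#> [1] 10
round(feats[1:3, c("volume_um3", "surface_area_um2", "sphericity",
                   "complexity", "mean_intensity_SnapTag")], 3)
#>   volume_um3 surface_area_um2 sphericity complexity mean_intensity_SnapTag
#> 1      0.805            5.040      0.830      1.747                 53.722
#> 2      0.751            5.140      0.778      2.127                 12.071
#> 3      0.663            3.902      0.943      1.193                 56.435
```

Row 2 is a dim (young-label, mean SnapTag intensity ≈ 12) tubule — low
sphericity, complexity above 2 — while row 3 is a bright punctum with
near-spherical shape (ψ = 0.94, MCI ≈ 1.2). `run_pipeline()` chains
simulation, segmentation, feature extraction, stratification and the
per-stratum Dunn test, writing label maps (16-bit TIFF), feature and
statistics tables (CSV), strata thresholds (JSON) and the fully resolved
configuration (YAML) into an output directory; re-running the same
configuration reproduces every numeric output.

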