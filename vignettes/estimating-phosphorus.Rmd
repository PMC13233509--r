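---
title: "Estimating plant phosphorus content from UAV imagery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating plant phosphorus content from UAV imagery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`uavppc` implements a complete desk-scale pipeline for estimating winter
wheat plant phosphorus content (PPC, g/kg dry matter) from paired UAV RGB and
six-band multispectral imagery: scene simulation, plot-ROI extraction,
spectral and texture feature computation, feature selection, and regression
with the standard remote-sensing accuracy metrics. This vignette explains the
underlying models, the tunable parameters, the numerical conventions, and
what the synthetic experiments do and do not demonstrate.

## The estimation problem

Phosphorus deficiency changes leaf pigments and canopy architecture, which in
turn shift canopy reflectance: P-starved wheat tends to be brighter in the
visible bands (450, 555, 660 nm) and at the lower red edge (720 nm), and
darker on the NIR plateau (750, 840 nm) where reflectance is driven by
healthy mesophyll and canopy density. A plot-level regression therefore links
image-derived features to PPC measured on destructive samples. Features come
in five families:

* **Colour indices (CI)** — 14 functions of mean RGB digital numbers: the
  raw channels $R, G, B$; the normalized shares $r = R/(R+G+B)$, $g$, $b$;
  and $BGI = b/g$, $BRI = b/r$, $GRI = g/r$, $CI\_GRVI = (g-r)/(g+r)$,
  $VARI = (g-r)/(g+r-b)$, $MGRVI = (g^2-r^2)/(g^2+r^2)$,
  $RGBVI = (g^2-rb)/(g^2+rb)$, $TGI = -0.5\,[190(r-g) - 120(r+b)]$.
* **Vegetation indices (VI)** — 12 functions of band reflectance, e.g.
  $NDVI = (\rho_{840}-\rho_{660})/(\rho_{840}+\rho_{660})$,
  $NDRE$, $MTCI$, $DVI$, $RVI$, $CI_{red\,edge} = \rho_{840}/\rho_{RE}-1$,
  $EVI$, $OSAVI$, and a reflectance-based $ExG$.
* **Fractional vegetation cover (FVC)** — the dimidiate (two-endmember)
  pixel model: per pixel
  $FVC = (NDVI - NDVI_{soil})/(NDVI_{veg} - NDVI_{soil})$, clipped to
  $[0,1]$ and averaged over the plot ROI.
* **Texture features (TF)** — eight grey-level co-occurrence matrix (GLCM)
  statistics (mean, variance, homogeneity, contrast, dissimilarity, entropy,
  second moment, correlation) per band, from a moving window.
* **Texture indices (TI)** — pairwise combinations of texture features
  from any bands/statistics:
  $NDTI = (T_1-T_2)/(T_1+T_2)$, $RTI = T_1/T_2$, $DTI = T_1-T_2$.

Three selectors rank these features on the training partition only (Pearson
correlation, random-forest impurity importance, RReliefF weighting), and
three regression families (random forest, RBF-kernel support vector
regression, K-nearest neighbours) map the selected features to PPC.
Accuracy is summarized by $R^2$, RMSE, and the relative prediction deviation
$RPD = SD/RMSE$, where $SD$ is the sample standard deviation of the observed
values in the evaluated partition; $RPD > 2$ conventionally indicates a
model usable for quantitative prediction. (Some published formulations print
an "SD" formula that is algebraically identical to the RMSE, which would
force $RPD \equiv 1$; this package uses the standard-deviation definition,
which is the only one consistent with reported RPD values above 1.)

## The synthetic trial

Real paired UAV/PPC campaigns are rarely public, so the package ships a
seeded generator that emulates a five-rate phosphorus trial:

* **Layout** (`field_layout()`): 5 P~2~O~5~ rates (0, 75, 120, 165,
  210 kg/ha) × 3 replicates = 15 plots on a soil background, each plot
  30 × 40 pixels at 0.5 m ground sample distance, with 4-pixel soil alleys.
* **PPC truth** (`simulate_ppc_truth()`): for stage $s$ and rate $x$,
  $PPC = \beta_s + g\,x/(x + h) + \varepsilon$. The stage baselines
  $\beta_{T1..T5} = 3.6, 3.2, 2.8, 2.4, 2.0$ g/kg decline from jointing to
  maturity, matching the dilution of tissue phosphorus as dry matter
  accumulates; the saturating (Michaelis-type) rate response with gain
  $g = 1.5$ g/kg and half-saturation $h = 60$ kg/ha reproduces the
  narrowing of treatment differences at high application rates;
  $\varepsilon \sim N(0, 0.08)$ g/kg stands for within-plot variability and
  assay error, which published trials do not quantify.
* **Reflectance** (`simulate_scene()`): each pixel mixes vegetation and
  soil endmember spectra by a per-pixel canopy cover. Cover rises with P
  rate ($0.45 + 0.40\,x/(x+h)$) and carries crop-row sinusoidal modulation
  (period 6 px, amplitude 0.08) plus spatially correlated Gaussian noise
  (sd 0.05, correlation length 3 px, from blurred white noise) so that GLCM
  features have non-degenerate, cover-dependent structure. The vegetation
  spectrum shifts linearly with PPC: negative sensitivities at
  450/555/660/720 nm and positive at 750/840 nm, so low-P plots are
  visibly brighter and NIR-darker. Additive sensor noise (sd 0.01
  reflectance) is applied per pixel and band, then values are clipped to
  $[0,1]$.
* **RGB** digital numbers are rendered from the 660/555/450 nm bands of the
  same latent canopy (scaled to DN 255 at reflectance 0.35, configurable
  gamma), not from an independently modelled second sensor; this keeps the
  colour indices informative without a second optical chain.

With all noise terms set to zero the construction is monotone: plot-mean
840 nm reflectance has rank correlation exactly +1 with PPC, which the test
suite asserts. What the generator does **not** emulate: shadows, weeds,
terrain relief, bidirectional reflectance effects, atmospheric variation,
sensor co-registration error, or any decoupling of cover from nutrient
status (drought, disease). Passing tests therefore demonstrate that the
pipeline's computations are correct and that the method recovers a known
monotone signal under realistic noise — not that the same accuracies would
be attained on field data.

## Extraction conventions

* **ROIs.** Plot polygons are buffered inward by 0.75 m by default (the
  midpoint of the commonly used 0.5–1 m range) to exclude edge
  disturbances; a pixel belongs to a mask when its centre falls inside the
  polygon. The inward offset is exact for convex rings (half-plane
  clipping); all generated plots are rectangles.
* **Aggregate-then-index.** Colour and vegetation indices are computed from
  plot-mean DN/reflectance, matching the usual practice of extracting ROI
  means before index computation. Per-pixel computation is available through
  `feature_rasters()` for inversion mapping.
* **Plot values are means.** Whether published workflows aggregate ROI
  pixels by mean or median is typically unstated; `zonal_mean()` uses the
  arithmetic mean and excludes missing pixels from numerator and
  denominator.
* **Red edge.** The camera has two red-edge bands (720, 750 nm) but the
  red-edge indices use a single $\rho_{RE}$; which band feeds them is a
  configuration choice (`red_edge`, default `"720"`, the band nearest
  common NDRE definitions). The two configurations coincide when the bands
  are numerically equal, which the suite asserts.
* **FVC endmembers** default to the scene-wide 5th/95th NDVI percentiles.
  Scene-wide (rather than per-plot) estimation keeps the soil endmember
  observable even for fully covered plots; endmembers can be supplied
  explicitly.
* **Zero denominators** anywhere in the index algebra yield `NA`, never
  infinities; features with missing values on training rows are dropped
  before selection with a warning, and the dropped set is recorded on the
  selection object.

## GLCM texture

The texture contract (`glcm_spec()`) is: quantization to 64 grey levels by
scene-wide per-band min–max scaling (per-window ranges would destroy the
comparability of the mean/variance textures across plots); a 3 × 3 moving
window; four directions (0°, 45°, 90°, 135°) at 1-pixel offset; symmetric
normalized co-occurrence tables; directional averaging. Statistic formulas
are the Haralick-style definitions with entropy in natural log
($0\ln 0 = 0$) and second moment as the angular second moment $\sum P^2$.
Numerical conventions: windows with zero grey-level variance return
correlation 0 (the 0/0 case); border pixels with incomplete windows are
missing (padding would bias entropy and second moment); directions without
valid pairs are excluded from the average. Texture indices enumerate **all**
ordered pairs of distinct features deterministically (48 × 47 = 2256 pairs
per family for six bands) rather than sampling "random band" pairs;
downstream selection prunes them, and determinism is preferred over
sampling. The moving-window engine is implemented in C++ (Rcpp) and is
verified, statistic by statistic, against a brute-force pair-enumeration
oracle on hundreds of random patches at tolerance 1e-10.

## Feature selection

All three selectors operate on training rows only — the suite asserts that
perturbing validation rows changes no score, scaler, or fitted model.

* **Pearson screening** retains features with $|r| \ge 0.5$ by default (the
  threshold used in published workflows is typically unstated; it is
  configurable, and `top_k` overrides it).
* **RF importance** ranks by impurity-reduction importance of a 100-tree
  regression forest grown with the same leaf/split settings as the modelling
  forest, and keeps the top 10 by default.
* **Relief.** The classical Relief algorithm is defined for binary
  classification; with a continuous target the regression variant
  (RReliefF) is the applicable member of the family and is what
  `relief_weights()` implements. Hyperparameters are not derivable from
  published descriptions and are declared as defaults: 10 nearest
  neighbours, iterations over every training instance (making the default
  fully deterministic), Manhattan distance on features scaled to $[0,1]$,
  and exponential rank-decay of neighbour influence (scale 10).

Ties are everywhere broken by (score descending, feature name ascending), so
rankings are permutations and reproducible bit-for-bit under a fixed seed.
Subset sweeps (`subset_sweep()`) return nested prefixes of a ranking,
supporting the usual top-10 … top-3 comparison grids.

## Modelling

The sample table is split 3:1 (training fraction 0.75, floor rule, seeded;
optional stratification by stage or treatment — whether published splits
were stratified is usually unstated, so the default is unstratified).
Features are z-scored with training statistics only; scaling is applied for
all three families (it is a no-op in effect for forests but keeps one code
path; it can be disabled per configuration). Model configurations follow
widely used settings: random forest with 100 trees, minimum leaf size 5, at
most 20 splits per tree, `mtry = max(1, floor(p/3))` unless set; SVM with
RBF kernel, $C = 10$, $\gamma = 0.1$, and $\epsilon = 0.1$ (the
$\epsilon$-tube width is rarely reported; 0.1 is the e1071 default);
KNN with $K = 7$. `tune_cv()` performs seeded 5-fold cross-validation on the
training rows over an explicit grid, minimizing mean fold RMSE; infeasible
grid points (e.g. more neighbours than fold samples) lose the comparison.
A constant training target degenerates every family to the constant
predictor.

`inversion_map()` applies a fitted model per pixel: features are recomputed
as rasters, standardized with the training scaler, and predicted. Features
defined only as plot aggregates (FVC) cannot be rasterized and are refused
by name; texture borders propagate as missing pixels. With the noise-free
generator the plot means of the inversion map rank plots identically to the
ground truth.

## Problem sizes and determinism

The shipped experiments use the 15-plot × 5-stage layout (75 samples), full
scenes of roughly 106 × 224 pixels, and all 6 891 features; a full
simulate–extract–select–model run takes a few seconds on one core, and the
repeated-seed studies (100-seed selector recovery, 20-seed end-to-end
recovery) a few minutes. Every random operation derives a named substream
seed from one global seed, so a single integer reproduces scenes, splits,
forests and reports exactly; scene rasters written to disk reproduce
identical MD5 digests across runs.

## Known limitations

* File I/O uses multi-page float TIFF with a JSON sidecar for geotransform
  and band names, and plain GeoJSON for ROIs; georeferencing metadata is
  carried but no projection handling, resampling or co-registration is
  performed — mismatched geotransforms are an error, as the inputs are
  assumed orthorectified and co-registered upstream.
* The inward polygon buffer is exact for convex rings only.
* The generator's cover–PPC coupling makes structural and spectral signals
  reinforce each other; on field data with decoupled stressors the
  selection outcomes and accuracies can differ materially.
* No uncertainty quantification beyond RPD; no wavelet/Gabor textures; no
  multi-distance GLCM; no dimensionality reduction before Relief (its known
  weakness on redundant high-dimensional inputs is inherited).
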