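---
title: "Time-series vector features for cultivated-land mapping: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-series vector features for cultivated-land mapping: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtvf)
```

This vignette is the package's own account of its science: the model and
its assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic-scene generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## 1. The classification model

### Time-series vectors and their five features

Cultivated land in a double-cropping landscape (winter wheat sown in
October, harvested in June; summer corn from June to September) has a
temporal reflectance trajectory unlike any other land-cover class: two
green-up peaks per agricultural year. Single-date spectra, in contrast,
overlap badly — in October a wheat field *is* bare soil, and senescent
grassland resembles both. The model therefore never classifies dates
individually. For each pixel, the values of one parameter $p$ (a spectral
band or a vegetation index) across the $T$ acquisition dates form an
ordered vector

$$\mathbf{V}_p = (p_1, p_2, \dots, p_T),$$

and each vector is reduced to five features. Three are order statistics:

$$\mathrm{Max}_p = \max_t p_t,\qquad \mathrm{Min}_p = \min_t p_t,\qquad
\mathrm{Ran}_p = \mathrm{Max}_p - \mathrm{Min}_p .$$

Two compare the vector with the all-ones reference $\mathbf{V}_0$:

$$\mathrm{Cos}_p =
  \frac{\sum \mathbf{V}_0 \mathbf{V}_p}
       {\sqrt{\sum \mathbf{V}_0^2 \, \sum \mathbf{V}_p^2}},
\qquad
\mathrm{Dis}_p = \sum (\mathbf{V}_0 - \mathbf{V}_p)^2 .$$

$\mathrm{Cos}_p$ is the cosine of the angle between the trajectory and
the constant vector: it is invariant to positive rescaling of the pixel's
whole series, which makes it robust to albedo and illumination
differences, and it responds to the *shape* of the season. $\mathrm{Dis}_p$
is the squared Euclidean distance from the reference and mixes amplitude
with shape.

Two transcription choices deserve a note. Some write-ups of this feature
family print the cosine without the square root in the denominator and
call the squared distance a "distance". This package implements the true
cosine by default (the quantity is named a cosine and must satisfy
$|\mathrm{Cos}| \le 1$); `cosine_form = "printed"` restores the literal
unrooted form for comparison. For the distance, the squared form is the
default — a strictly monotone transform of the Euclidean distance is
indistinguishable to tree-based classifiers, which split on thresholds —
and `distance_form = "euclidean"` takes the root.

Because $\mathbf{V}_0$ is constant, all five features are invariant to
permuting the acquisition order (the tests assert this). Temporal
ordering information therefore enters only through *which* acquisitions
are included; the features capture the season's distribution of values,
not its sequence. This is a deliberate property of the method, not an
oversight: the double-peak signature shows up in the relation between
extremes, mean level and spread.

### The parameter bank

The default bank is the 13 Sentinel-2 MSI band names (B1–B8, B8A,
B9–B12, including the cirrus band B10, so that the band list is fully
configurable and defaults to the canonical 13) plus 23 vegetation
indices: SAVI, TSAVI, MSAVI, MSAVI2, DVI, RVI, PVI, IPVI, WDVI, TNDVI,
GNDVI, GEMI, ARVI, NDI45, MTCI, MCARI, S2REP, IRECI, PSSR, NDVI,
NDVI705, EVI and EVI2 (aliases IECI → IRECI, PSSRA → PSSR,
REIP → S2REP are accepted). Formulas follow the standard Sentinel-2
toolbox conventions; every empirical constant is exposed:

| constant | meaning | default |
|---|---|---|
| `L` | SAVI soil-adjustment factor | 0.5 |
| `soil_slope`, `soil_intercept` | soil line (TSAVI, PVI, MSAVI, WDVI) | 0.5, 0.5 |
| `X` | TSAVI adjustment | 0.08 |
| `gamma` | ARVI aerosol coefficient | 1.0 |

Soil-line defaults are generic rather than site-calibrated; users mapping
a real site should fit them to local bare-soil pixels and pass them via
`register_default_indices(constants = ...)`.

Indices are evaluated per date and pixel on normalized reflectance
(bands and indices alike — computing indices on raw digital numbers
would silently change every non-linear formula). Undefined arithmetic
(zero denominators, e.g. MTCI at $B5 = B4$) yields `NaN`, which is
counted per index and invalidates the affected pixel for that parameter;
rows containing `NaN` never reach training. One guard: the TNDVI
radicand $\mathrm{NDVI} + 0.5$ is clamped at zero, because over open
water $\mathrm{NDVI} \approx -0.5$ and a literal `NaN` rule would
invalidate essentially the whole water class.

### Importance ranking and group selection

A random forest accumulates, for feature $f$, the Gini impurity decrease
$\Delta G = G - (G_L + G_R)$ over every split that uses $f$, summed over
all trees: $I_f$. The importance score is the normalized value
$S_f = I_f / \sum_f I_f$, so scores sum to one and average $1/180$ over
the full bank. The implementation delegates the impurity accounting to
the `randomForest` package's mean-decrease-in-impurity accumulator; note
that standard implementations weight child impurities by the child
sample fractions, whereas the plain expression above does not — the
library convention is used here and the discrepancy is documented rather
than resolved, since it affects neither the ordering in practice nor the
normalization.

Features are then grouped by strictly decreasing score thresholds
(default 0.1, 0.04, 0.02, 0), giving nested groups A ⊆ B ⊆ C ⊆ D. The
thresholds mirror visually chosen "knee" points of a typical importance
profile; automatic knee detection is deliberately not implemented — the
grouping is a reading aid, and the selection step below is what actually
decides. An empty top group (no feature above 0.1, common on easy
scenes) is dropped with a warning and the remaining groups are
relabelled.

For every group and every tree count on a grid (default 50–1000 by 50),
a forest is fitted on a stratified 70 % portion of the training samples;
its out-of-bag error (estimated internally on the ≈ 36.8 % of samples
each tree never saw — the in-bag bootstrap covers ≈ 63.2 % of distinct
samples, $1 - e^{-1}$ in the limit) and its prediction accuracy on the
held-out 30 % are recorded. "Prediction accuracy" is measured on this
seeded stratified hold-out because validation pixels must stay
untouched until the final assessment. The selected group maximizes peak
hold-out accuracy, with ties broken by lower OOB error and then by fewer
features; the tree count is the smallest on the grid within
`plateau_tol` (default 0.002 absolute accuracy) of that group's peak —
more trees past the plateau only cost time.

`mtvf()` wraps ranking, grouping, curve tracing, selection and the final
forest into one fitted object with `print`, `summary`, `predict`,
`plot` and `importance` methods.

### Prediction

Full scenes are classified in tiles (configurable `tile_rows`) so memory
stays bounded. Per pixel the class is the argmax of tree votes; ties
break deterministically to the earlier class in the legend, which makes
tiled prediction output-invariant — the stock random tie-break would
make the map depend on tile size. Nodata propagates: a pixel invalid at
any date, or with any undefined selected feature, stays nodata in the
map.

### Comparators

The Gaussian maximum-likelihood classifier is implemented from first
principles: per class a mean vector and covariance matrix, prediction by
the largest discriminant
$g_i(x) = \ln \pi_i - \tfrac12 \ln |\Sigma_i|
- \tfrac12 (x-\mu_i)^\top \Sigma_i^{-1} (x-\mu_i)$,
ties to the earlier class (logged). The covariance ridge is scaled to
the mean feature variance and escalated tenfold until the Cholesky
factorization succeeds, because classes with fewer samples than feature
dimensions have rank-deficient covariance. With shared covariance and
equal priors this reduces exactly to nearest-mean (Mahalanobis)
classification, which the tests assert. The SVM (`e1071::svm`, radial
kernel) and ANN (`nnet::nnet`, one hidden layer, standardized inputs,
seeded start) are thin adapters with developer-recommended defaults, as
is appropriate for reference comparators; `compare_models()` trains all
of them on byte-identical splits (fingerprint logged) and reports OA,
cultivated-class UA/PA and kappa side by side.

## 2. Accuracy assessment

Confusion matrices are oriented rows = reference, columns = prediction —
stated explicitly because the literature is inconsistent — so producer's
accuracy $PA_i = c_{ii}/\text{row}_i$ is recall and user's accuracy
$UA_i = c_{ii}/\text{col}_i$ is precision. Overall accuracy is
trace/total and $\kappa = (p_o - p_e)/(1 - p_e)$ with
$p_e = \sum_i \text{row}_i \cdot \text{col}_i / N^2$. Reports keep
proportions internally and print percentages with two decimals. The
binary cultivated / non-cultivated evaluation merges all non-cultivated
classes *before* tallying; merging after tallying gives the identical
matrix (asserted), so either reading of a sub-area protocol is
reproduced. Empty reference rows yield `NaN` PA with a warning rather
than an error, and samples falling off-grid or on nodata are excluded
and counted separately.

## 3. The synthetic scene generator

The generator exists so that every stage — raster I/O, index evaluation,
feature extraction, selection, classification, assessment — can be
validated end to end without external imagery. It emulates:

- a **patch mosaic** via seeded Voronoi tessellation of random sites,
  classes assigned to sites in configurable proportions (defaults:
  cultivated 0.45, woodland 0.15, grassland 0.12, artificial 0.12,
  water 0.08, bare 0.08 — a plains agricultural landscape);
- **class phenology**: per class a greenness curve on the
  October-to-September month axis mixes a vegetation and a soil
  end-member spectrum per band. Cultivated land has two Gaussian
  green-up pulses (spring wheat peak, late-summer corn peak), woodland
  one broad summer peak over a dark understory, grassland a
  lower-amplitude peak over brighter soil; water is persistently dark in
  the near infrared, artificial and bare surfaces are temporally flat at
  different brightnesses. The cultivated NDVI profile has exactly two
  interior local maxima (asserted analytically in the tests);
- **albedo variability**: a per-pixel log-normal brightness factor
  (sd 0.15), constant over time, multiplies the whole series. This is
  what makes single-date classification genuinely hard — without it,
  class-constant brightness would be a give-away no real scene offers —
  while leaving the scale-invariant Cos features untouched;
- **mixed pixels**: within a configurable boundary width (default 1
  pixel) the two adjacent class profiles are mixed linearly, up to 50/50
  on the boundary itself;
- **sensor noise**: i.i.d. additive Gaussian reflectance noise
  (default sd 0.02). Values are kept in (0, 1) by a monotone soft
  saturation rather than a hard clamp — truncation would create exact
  ties between bands and hence artificial zero denominators in ratio
  indices.

Defaults are 256 × 256 pixels, 12 monthly dates, the 13-band set, mean
patch area 2500 px (≈ 500 m field blocks at 10 m resolution). Sampling
follows the supervised-classification rule of thumb of ten times the
band count per class for training (130), with the scarce water and bare
classes capped at 70, and 300 validation pixels per class, drawn
stratified and disjoint from training.

What the generator does **not** emulate: sensor point-spread functions,
atmospheric residuals and cloud contamination, spatially correlated
noise, within-class phenological diversity (sowing-date spread,
irrigation differences), terrain illumination coupled to topography, and
orchards — the class that most plagues real cultivated-land mapping.
Passing tests on synthetic scenes therefore demonstrate the pipeline's
internal correctness and the discriminative power of temporal-shape
features under controlled conditions, not operational accuracy on real
imagery, which depends on factors the generator idealizes away.

On the default scene, the fitted pipeline reaches validation overall
accuracy above 0.95 and beats a single-date baseline (random forest on
the 13 band values of the first, October, acquisition — the annual time
node, when a wheat field is spectrally bare soil) by some twenty
percentage points; the acceptance tests assert the ≥ 0.95 level and a
≥ 5-point margin. Accuracy degrades monotonically as noise grows and
mixed-pixel counts grow with boundary width (both asserted as seeded
trend tests).

## 4. Rasters, grids and formats

No geospatial raster stack is assumed. Scenes are stored as per-date
multi-page TIFFs of 16-bit digital numbers (reflectance × 10 000, the
L2A convention, one greyscale page per band — baseline TIFF caps the
samples per pixel, so pages are the portable representation), which
round-trip bit-exactly. Grid metadata (pixel-center origin, pixel size,
CRS string) travels in the JSON manifest next to the rasters; rasters
are north-up, single-CRS. Bands at a coarser resolution are resampled to
the finest grid bilinearly (`pracma::interp2`; nearest-neighbour by
flag). Normalization is `scale10000` by default — index formulas assume
physical reflectance — with `minmax_per_band` (pooled over all dates,
idempotent, erroring on constant bands) as the alternative. A pixel with
nodata at any date is invalid for feature extraction; with near-monthly
cloud-screened acquisitions this is the conservative choice, and gap
filling is explicitly out of scope (as is any temporal smoothing —
Savitzky–Golay filters or harmonic fits would alter the vectors the
method is defined on).

## 5. Problem sizes and reproducibility

All randomness flows from one integer seed through named substreams
(mosaic, brightness, noise, sampling, ranking, splits, forests), and
every artifact-writing stage records the resolved seed. The test suite
and examples run scenes between 24² and 256² pixels; the end-to-end
acceptance check uses the full default 256 × 256 scene with the complete
50–1000 tree grid, chosen so that the whole suite completes in about a
minute on a single core while still exercising the pipeline at a
realistic desk scale. The bootstrap experiment behind the out-of-bag
fractions uses 200 resamples of size 10 000, which pins the in-bag
percentage to within ±0.5 points of $100(1 - e^{-1}) \approx 63.2$.

## 6. Known limitations

- The five features discard acquisition *order*; phenologically distinct
  classes with identical value distributions would be inseparable. Real
  double-cropping landscapes do not present this pathology, but a
  single-peak crop with the same amplitude and duration as grassland
  would require additional features.
- Gini importance is biased toward features with many split points and
  correlated features share credit unpredictably; the group-selection
  step (which evaluates groups by hold-out accuracy, not by score) is
  the mitigation. Permutation importance is out of scope.
- The MLC comparator with strong ridge regularization on
  high-dimensional groups is effectively a shrunken quadratic
  discriminant; its published form assumes many more samples than
  features.
- `minmax_per_band` normalization couples dates (the pooled extremes),
  so adding an acquisition changes earlier features slightly; the
  default `scale10000` has no such coupling.
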