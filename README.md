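# mtvf — annual cultivated-land mapping with time-series vector features

`mtvf` classifies satellite image time series into land-cover maps, aimed
at annual cultivated-land mapping over intensively farmed landscapes
(winter wheat–summer corn double cropping and its neighbours: woodland,
grassland, water, artificial surfaces, bare land). Instead of feeding raw
per-date spectra to a classifier, it treats each pixel's temporal sequence
of every spectral band and vegetation index as a *vector* and reduces it
to five features, which widens the separation between land-cover types
whose single-date spectra overlap.

## The method

For a pixel and a parameter *p* (one of B spectral bands or K vegetation
indices), the observations at the T acquisition dates form the time-series
vector **V**ₚ = (p₁, …, p_T). With the all-ones reference vector
**V**₀ = (1, …, 1), five features summarise **V**ₚ:

- Maxₚ = max(p₁, …, p_T),  Minₚ = min(p₁, …, p_T),  Ranₚ = Maxₚ − Minₚ
- Cosₚ = Σ **V**₀·**V**ₚ / √(Σ **V**₀² · Σ **V**ₚ²) — the cosine of the
  angle to the reference (scale-invariant temporal shape)
- Disₚ = Σ (**V**₀ − **V**ₚ)² — the squared distance from the reference

With 13 Sentinel-2-style bands and a bank of 23 vegetation indices
(NDVI, EVI, SAVI, red-edge indices, …) this yields a 180-column feature
table. A random forest ranks the features by normalized Gini importance
S_f = I_f / Σ I_f (mean decrease in impurity), features are grouped at
descending score thresholds (default 0.1, 0.04, 0.02, 0 — nested groups
A ⊆ B ⊆ C ⊆ D), and the group with the highest hold-out prediction
accuracy and smallest out-of-bag error over a grid of tree counts is
selected before the final forest is trained. Accuracy is assessed by
confusion matrix: overall accuracy, producer's and user's accuracy per
class, and the kappa coefficient, plus a binary cultivated /
non-cultivated evaluation.

A Gaussian maximum-likelihood classifier (implemented from first
principles), an SVM and a single-hidden-layer neural network are included
as comparators trained on byte-identical sample splits, and a seedable
synthetic-scene generator with class-specific phenology profiles makes
the whole pipeline testable without external imagery.

## Worked example

```r
library(mtvf)

scene   <- generate_scene(scene_config(width = 128, height = 128,
                                       mean_patch_area = 1000, seed = 5))
samples <- draw_samples(scene, seed = 5)
indices <- evaluate_indices(scene$cube)

train_px <- samples[samples$role == "train", ]
train <- label_features(
  build_feature_table(scene$cube, indices, train_px[c("row", "col")]),
  train_px)

fit <- mtvf(train, seed = 5)
summary(fit)
```

```
MTVF fit summary
----------------
Top features by importance score:
    feature importance      score rank
   PSSR_Dis   22.47346 0.04147935    1
   IPVI_Dis   22.33383 0.04122164    2
    RVI_Dis   20.39631 0.03764555    3
   NDVI_Dis   17.63924 0.03255682    4
     B8_Cos   16.85060 0.03110123    5
  GNDVI_Dis   16.82269 0.03104970    6
    B12_Ran   16.66897 0.03076599    7
    B11_Ran   14.41427 0.02660448    8
 MSAVI2_Max   13.18709 0.02433947    9
   ARVI_Dis   11.56041 0.02133709   10

Group sizes: A=2, B=10, C=180
Selected group B: 10 features, 50 trees
Final forest OOB error: 0.0167
Peak hold-out prediction accuracy: 1.0000
```

The importance ranking is dominated by `Dis` and `Cos` features of
near-infrared/red ratio and normalized-difference indices — the temporal
*shape* of the vegetation signal — rather than by raw extreme values, and
the selection keeps a 10-feature group. Classifying the scene and scoring
it against the validation pixels:

```r
map    <- predict_map(fit, scene$cube, indices)
report <- accuracy_metrics(confusion(map, samples))
report
```

```
Overall accuracy: 97.39%   kappa: 0.9687   (n = 1800)
      class     PA      UA reference_pixels
 cultivated 94.33%  98.95%              300
   woodland 98.00%  98.33%              300
  grassland 99.33%  91.98%              300
      water 98.00% 100.00%              300
 artificial 97.33%  97.66%              300
       bare 97.33%  97.99%              300
```

PA (producer's accuracy) is the fraction of reference pixels of a class
recovered by the map; UA (user's accuracy) is the fraction of mapped
pixels that truly belong to the class. `run_pipeline()` wraps the whole
chain (including the comparator benchmark with `compare = TRUE`), and
`inst/cli/mtvf` exposes it as shell subcommands
(`simulate | extract-features | rank | select | train | classify |
evaluate | compare | run`).

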