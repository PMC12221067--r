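# fasftle

An R pipeline for MRI-based detection of temporal lobe epilepsy (TLE):
preprocessing, fuzzy tissue segmentation with anatomical labelling,
handcrafted feature extraction, metaheuristic feature selection, an
attention-based neural classifier with saliency maps, and a full
evaluation suite. Every stage can be exercised on seeded synthetic brain
phantoms with known ground truth, so the whole pipeline runs and is
testable without any external imaging data.

It is intended for methods researchers who want a transparent, fully
inspectable reference implementation of this class of pipeline — every
numerical step, including the neural network's training loop, is plain R
code in this package.

## The pipeline

1. **Preprocessing** — skull stripping (three-class Otsu threshold,
   morphological opening/closing, largest component, hole filling), bias
   field correction under the multiplicative model *I = B·C* (log-domain
   alternation between tissue-level explanation and masked Gaussian
   smoothing, with a monotone energy trace), min–max normalisation
   `(x − min)/(max − min)`, and median filtering.
2. **Fuzzy-possibilistic c-means (FPCM) segmentation** — combines
   row-normalised fuzzy memberships
   `U[i,C] = 1 / Σ_K (D[i,C]/D[i,K])^(2/(M−1))`
   with possibilistic typicalities
   `α[i,C] = 1 / (1 + (D[i,C]/η_C)^Q)`, centres updated by the
   joint-membership-weighted mean; each voxel's label is
   `argmax_C U[i,C]·α[i,C]`. Cluster ids are sorted by centre intensity
   (CSF/GM/WM ordering is deterministic).
3. **Atlas labelling** — nearest-neighbour label transfer through a
   user-supplied 4×4 voxel affine, with per-(region × tissue) statistics.
4. **Feature extraction** — 256-bin local binary pattern histograms,
   intensity moments (mean, population variance, raw third central
   moment), and shape descriptors (area, boundary-pixel perimeter,
   moment-ellipse eccentricity, compactness = perimeter²/area) per region.
5. **DGWO feature selection** — a hybrid dipper-throated / grey-wolf
   swarm over the unit cube; positions are thresholded into feature
   masks and scored by cross-validated classification error of a
   nearest-centroid reference classifier (pluggable). An exhaustive
   search oracle is included for problems with ≤ 16 features.
6. **HAETN classifier** — depthwise-separable convolution encoder with
   CBAM channel/spatial attention per slice, BiLSTM with temporal
   attention over the slice sequence, a transformer encoder block,
   dense + softmax head; trained by seeded SGD with momentum and
   gradient clipping on a package-internal reverse-mode autodiff engine
   (gradient-checked against finite differences). Grad-CAM saliency maps
   (element-wise high-resolution variant) explain predictions.
7. **Evaluation** — confusion counts, the nine standard metrics
   (accuracy, precision, sensitivity, specificity, F1, MCC, NPV, FPR,
   FNR), ROC/AUC with tie handling, and stratified k-fold
   cross-validation with per-fold and mean ± sd reporting.

## Worked example

```r
library(fasftle)

# a seeded phantom: 3-tissue ellipsoidal brain, skull shell, bias, noise
ph <- make_phantom(shape = c(48, 48, 24), seed = 1,
                   bias_amplitude = 0.15, gaussian_sd = 0.02,
                   impulse_fraction = 0.01)

pre <- preprocess_pipeline(ph$vol, pipeline_config(seed = 1))
seg <- fpcm_segment(pre$vol, mask = pre$intermediates$mask,
                    params = list(c = 3))
tidy(seg$state)
#> # A tibble: 3 × 3
#>   cluster center      eta
#>     <int>  <dbl>    <dbl>
#> 1       1  0.193 0.00137
#> 2       2  0.398 0.000748
#> 3       3  0.602 0.000572
```

The three centres recover the phantom's equally spaced class means
(0.25 / 0.50 / 0.75 in raw units; min–max normalisation against the
bright residual extremes rescales them to ≈ 0.19 / 0.40 / 0.60 while
preserving their spacing). The darkest cluster is CSF-like, the
brightest WM-like; `η` is the per-cluster possibilistic scale estimated
from the membership-weighted mean squared distance.

```r
atlas <- make_toy_atlas(c(48, 48, 24), n_regions = 4)
lab <- aal_label(seg$labels, atlas)
head(lab$stats, 3)
#> # A tibble: 3 × 4
#>   region_id region             tissue voxels
#>       <int> <chr>               <int>  <int>
#> 1         1 temporal_lobe_like      1   1596
#> 2         1 temporal_lobe_like      2    890
#> 3         1 temporal_lobe_like      3    141
```

Feature selection on a synthetic table with two informative features
hidden among eight noise features:

```r
tbl <- make_feature_dataset(n_per_class = 25, n_informative = 2,
                            n_noise = 8, effect_size = 4, seed = 4)
sel <- dgwo_select(tbl, list(n_agents = 10, max_iter = 30, seed = 4))
glance(sel)
#> # A tibble: 1 × 4
#>   best_fitness n_selected n_features iterations
#>          <dbl>      <int>      <int>      <int>
#> 1            0          2         10         30
```

The selector recovers exactly the two informative columns
(cross-validated error 0). The full end-to-end run — phantom cohort with
lesions planted in the temporal-lobe-like region, preprocessing,
segmentation, labelling, features, selection, classifier training and
k-fold evaluation — is one call:

```r
res <- run_pipeline(pipeline_config(seed = 1), n_per_class = 8)
res$cv$folds     # per-fold metric table
glance(res$cv)   # mean ± sd summary
```

`autoplot()` methods exist for FPCM states (objective trace), selection
results (best-so-far error), evaluation reports (ROC) and trained
models (loss/accuracy history); `plot_slice()` renders volumes and label
maps.

A thin command-line shell over these functions ships in
`inst/cli/fasf-tle.R` (`preprocess`, `segment`, `label`, `features`,
`select`, `evaluate`, `pipeline`, `synth` subcommands).

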