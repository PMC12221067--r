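---
title: "Models and methods behind the fasftle pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the fasftle pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science in each stage:
the models, their assumptions, the tunable parameters and their defaults,
the numerical choices made where the design was genuinely open, and what
the synthetic phantoms do and do not demonstrate about real MRI data.

## Preprocessing

**Skull stripping.** The phantom regime this stage is built for is a
bright brain, a thin bright skull shell, and a dark gap between them.
Foreground is thresholded with the *lower* threshold of a two-threshold
(three-class) Otsu: with background, several tissue classes and a shell
present, the single-threshold Otsu regularly lands between tissue
classes rather than between background and tissue. The mask is then
cleaned by a morphological opening (erode radius 1, keep the largest
face-connected component, dilate back): the opening removes
salt-impulse speckles and the one-voxel bridges they form across the
brain/shell gap. Taking the largest component *before* the closing (ball
radius `morph_radius`, default 2) matters: closing first would weld
brain and shell into one component whenever the gap is thinner than
twice the radius. Hole filling completes the mask. An image with no dark
background at all (every voxel positive) is treated as all brain. The
threshold method can be switched to a plain quantile
(`threshold_quantile`).

**Bias field correction.** The scanner inhomogeneity model is
multiplicative, `I = B · C`, with `B` smooth and positive. The estimator
works on the log image over the positive mask and alternates two steps:
(i) explain the current corrected image by a small set of tissue levels
(`n_classes = 3`, quantile-initialised Lloyd iterations — deterministic),
and (ii) absorb the smooth part of the unexplained residual into the
log-bias via masked Gaussian smoothing at `smoothing_sigma_mm`
(default 8 mm; normalised convolution so the brain boundary does not
bleed). The energy is the sum of squared residuals after step (i); a
step is only accepted if it lowers the energy, so the recorded trace is
non-increasing by construction, and the iteration stops at `max_iter`
(default 30) or when the relative decrease falls below `tol` (1e-4).
A bias-free piecewise-constant image is an exact fixed point: the class
levels explain it fully and `B` stays at 1. The log-bias is gauge-fixed
to mean zero over the mask (the overall intensity scale is not
identifiable in a multiplicative decomposition). This estimator is a
deliberately simple, testable realisation of the energy-minimisation
idea; it is not a replication of any particular published corrector.

**Normalisation and filtering.** Min–max normalisation is
`(x − min)/(max − min)` over the whole volume; a constant image maps to
zeros with a warning. It is idempotent, and it is sensitive to extreme
values by definition — on the phantoms, residual salt voxels compress
the tissue means by a visible factor, which is intended: the corruption
is what makes the stage nontrivial. The median filter uses odd windows
per axis (default 3³) with symmetric reflect padding, so outputs are
always order statistics of inputs and edges survive while impulses do
not.

## FPCM segmentation

Each in-mask voxel `i` carries a fuzzy membership row
`U[i,C] = 1 / Σ_K (D[i,C]/D[i,K])^(2/(M−1))` (rows sum to 1; a voxel at
zero distance is assigned crisply) and a possibilistic typicality
`α[i,C] = 1 / (1 + (D[i,C]/η_C)^Q)` which, unlike `U`, does not force
competition between clusters and therefore discounts outliers. Centres
move to the joint-weighted mean
`V_C = Σ α^Q U^M x / Σ α^Q U^M`, and the objective
`J = Σ_i Σ_C (U^M + α^Q) D²` is tracked per iteration; iteration stops
when `|ΔJ| < ε` (default 1e-5) or `max_iter` (100).

Numerical choices worth knowing:

* `η_C` is estimated once, after five fuzzy-only warm-up sweeps, as the
  membership-weighted mean squared distance (scaled by `eta_scale`,
  default 1), with a floor of 1e-6 against degenerate clusters.
* The product-weighted centre update is not an exact coordinate
  minimiser of the summed objective, so the raw alternation can drift
  `J` upward by ~1e-5 near convergence. The implementation therefore
  damps each centre step towards the update's candidate and accepts it
  only if `J` does not increase; an unavoidable uptick is treated as
  convergence. All updates remain exactly the closed forms above, and
  the recorded trace is non-increasing by construction.
* Cluster identity is fixed by sorting centres ascending, so label 1 is
  always the darkest tissue (CSF-like on T1-like phantoms). Label ids
  are therefore stable across runs and seeds.
* Initialisation is deterministic by quantiles (`(k − 0.5)/c`); a seeded
  kmeans++-style alternative exists for multi-modal inputs.
* Distances are Euclidean on intensity; the same code accepts
  multi-column voxel feature vectors unchanged.
* `c` defaults to 3 (CSF/GM/WM); nothing in the implementation depends
  on that choice.

On two-class mixtures with means 0.25/0.75 and sd 0.03 the recovered
centres sit within 0.02 of truth with ≥ 99% label accuracy across
seeds; at `M = 1.05` memberships become near-crisp, the hard-limit
behaviour of fuzzy clustering.

**Atlas labelling** maps each subject voxel through a user-supplied 4×4
affine into atlas voxel coordinates (0-based throughout, the NIfTI
convention) and samples the atlas label by nearest neighbour — labels
are categorical, so no interpolation is meaningful. Out-of-atlas voxels
get region 0, and a (region × tissue) voxel-count table is produced.
Registration itself (deformable or otherwise) is out of scope; the
affine is an input.

## Handcrafted features

Per region, on the region's mid slice (the median of slices where the
region is present — configurable in principle, and recorded in the
feature names):

* **LBP**: each interior pixel compares its 8 neighbours (clockwise from
  top-left, weights 2⁰…2⁷, `s(x ≥ 0) = 1`) against the centre; the
  256-bin histogram is normalised to sum 1. The code depends only on
  intensity order, so the histogram is invariant under monotone
  increasing maps — a property the tests assert.
* **Intensity moments**: mean, population variance (1/n), and the raw
  third central moment — not standardised skewness. The population
  normalisation is kept deliberately even though sample variance is more
  common, because the moment definitions are part of the feature
  contract.
* **Shape**: area (pixel count of the largest 4-connected component),
  perimeter (count of foreground pixels with a background 4-neighbour;
  the image border counts as background), eccentricity from the
  moment ellipse (`C/A` with `A = 2√λ₁`), and compactness
  `perimeter²/area`. The coordinate covariance includes the 1/12
  unit-square pixel extent, which keeps eccentricity strictly below 1
  for one-pixel-wide lines and makes a single pixel perfectly round —
  without it the invariant `0 ≤ e < 1` is violated by any straight
  line. Because the perimeter is a boundary-pixel count rather than an
  arc length, compactness values are comparable only within this
  convention.

"Colour" features operate on grayscale intensity; MRI is single-channel.

## DGWO feature selection

Agents live in `[0,1]^d`; a mask is `position > 0.5` (strict), and its
fitness is `1 − stratified k-fold CV accuracy` (k = 3, fixed fold seed)
of a nearest-centroid classifier on the selected columns, standardised
per training fold. The empty mask scores 1.0. Nearest-centroid was
chosen as the reference evaluator because it is deterministic, has no
tuning parameters, and costs microseconds — the wrapper's point is the
search, not the classifier — and any
`evaluator(X_train, y_train, X_test)` callback can replace it.

Each iteration draws `R ~ U(0,1)`: below 0.5 the whole swarm takes a
grey-wolf siege step (per-component `a = 2·l·r₁ − l` with `l` linear
2→0, `c = 2·r₂`, candidate positions from the three leaders averaged),
otherwise a dipper-throated flying step with persistent speeds
(`BS′ = c₃·BS + c₄·r₁·(best − x) + c₅·r₁·(gbest − x)`, `c₃` linear
0.9→0.4, `c₄ = c₅ = 1.5`). The swimming update
(`best − c₁·|c₂·best − x|`) is exposed and used in the pure baseline
mode. Coefficient schedules are declared defaults — the method's source
only states that they vary with iteration and randomness — and all are
configurable. Positions are clipped to the cube after every update;
fitness ties break by fewer selected features, then lower agent index;
the best-so-far trace is monotone by construction, and the whole run is
a deterministic function of (seed, config, table).

The exhaustive oracle enumerates all nonempty masks (refusing d > 16)
with the same evaluator and fold seed. On planted two-informative-eight-
noise problems (standardised mean difference 4, n = 50), the selector
reaches the exhaustive optimum's error within 0.02 in at least 8 of 10
seeded runs — the search-quality contract the tests enforce.

## The HAETN classifier

The serial pipeline per input sequence of T slices:

1. per slice: depthwise 3×3 convolution (one kernel per input channel)
   → 1×1 pointwise mixing to `conv_filters` channels → ReLU → 2×2 max
   pool → CBAM (channel attention: sigmoid of a shared MLP over global
   average and max descriptors; then spatial attention: sigmoid of a
   small convolution over the channel-wise average/max maps of the
   refined tensor);
2. per-slice embedding = concatenation of global **average** and global
   **max** pooling of the CBAM output. The max half is what lets a
   small, localised lesion survive into the embedding at full contrast
   instead of being diluted by the spatial average;
3. an embedding LayerNorm, then sinusoidal positional encodings added.
   The LayerNorm keeps the encoder output on the same scale as the
   unit-amplitude encodings; without it the position signal swamps the
   content signal at desk-scale widths and training stalls at chance;
4. BiLSTM (hidden width `lstm_hidden` per direction, forget bias
   initialised to 1) over the embedding sequence, concatenating forward
   and backward states;
5. temporal attention pooling: `e_t = u᷀ tanh(W_a h_t + b_a)`,
   `α = softmax(e)`, context `v = Σ α_t h_t`. The score is reduced to a
   scalar by a learned projection `u` (the score width is otherwise
   unconstrained; it defaults to `lstm_hidden`);
6. a transformer encoder block applied to `v` as a length-1 sequence —
   the serial reading of an architecture diagram that places the
   transformer after the attention-pooled BiLSTM. Its self-attention is
   then trivially a weight of 1, but the FFN, residual and LayerNorm
   still act. The block uses the single-residual form
   `O = LayerNorm(X + FFN(Attention(X)))` as specified, with the
   conventional two-residual layout behind `two_residual = TRUE`.
   Multi-head attention is fully implemented (per-head scaled
   dot-product, heads concatenated, output projection) and exposed, and
   is exercised on real sequences in feature-sequence mode and in its
   own tests;
7. optionally, a vector of handcrafted (selected) features concatenated
   to the transformer output (`fuse_handcrafted`, default off — where
   the selected features enter the network is an interpretation, so it
   is a switch rather than a baked-in choice);
8. dense(`dense_units`) + ReLU + dropout, then a softmax head.

Published-scale defaults are kept in the configuration (64 conv
filters, kernel 3, pool 2, 128 LSTM units, 8 heads, 2048 FFN units,
dropout 0.1/0.5, dense 64, batch 32, momentum 0.9); tests and the
bundled experiments run width-reduced instances (4 filters, 8 LSTM
units, 2 heads, 16 FFN units, dense 8), which the width-scaling
contract guarantees are valid models. `attn_heads` must divide the
model width `2·lstm_hidden`; the embedding width must be even for the
sinusoidal encoding.

**Training** is plain SGD with momentum (optionally a per-epoch
momentum schedule) on the cross-entropy, with global-norm gradient
clipping (default 1) — without clipping the desk-scale model reaches
separation and then collapses on some seeds. All gradients come from a
package-internal reverse-mode autodiff tape whose every operation is
verified against central finite differences in the test suite; there is
no external deep-learning dependency. Initialisation, batch shuffling,
dropout and the stratified validation split all flow from the config
seed, and execution is single-threaded, so same-seed retraining is
bit-identical — a property the tests assert rather than assume.

**Grad-CAM** reads the gradient of the target-class logit at the CBAM
output of each slice and combines it with the activations element-wise
before rectification (`relu(Σ_c ∂y/∂A_c ⊙ A_c)`, the high-resolution
CAM variant), normalised per slice to [0,1] and upsampled to the input
size. The classical spatially-averaged channel weights are misleading
here: with global max pooling in the encoder, class evidence is carried
by a few spatial positions, and averaging the gradient over space
cancels it (on some seeds the averaged variant localises the planted
lesion in under 10% of slices, the element-wise form in ≥ 90%).
Localisation is a property of a *converged* detector; saliency analyses
in the acceptance script therefore use the fully trained model.

## Evaluation

Class 1 (TLE) is the positive class throughout. The nine metrics follow
their standard formulas; any ratio with a zero denominator is reported
as `NA` with a warning, never silently as 0 or 1, because silent
defaults corrupt fold aggregates. `FPR = 1 − specificity` and
`FNR = 1 − sensitivity` hold exactly by construction. The ROC is built
from all distinct score thresholds with ties grouped — constant scores
therefore trace the chance diagonal with AUC 0.5 — and the trapezoid
AUC equals the concordant-pair (Mann–Whitney) statistic, cross-checked
in the tests both against a brute-force pair count and against an
established independent implementation. Stratified k-fold evaluation
trains a fresh model per fold (leak-free; fold models standardise
features with training-fold statistics) and reports per-fold rows plus
mean ± sd.

## Synthetic study conditions

The generators define the regimes every contract is tested under:

* `make_phantom()`: ellipsoidal brain (semi-axes 0.36 of the grid) with
  three nested tissue shells at means 0.25/0.50/0.75 (sd 0.03 — at
  least two sds of separation, the separable preset), a dark gap and a
  bright shell (0.9), a smooth multiplicative bias field `exp(g)` with
  controllable amplitude and smoothness, salt-and-pepper impulses (the
  regime the median filter removes) and Gaussian noise. Intensities live
  in [0,1] before corruption so normalisation is exercised nontrivially.
  All ground truths (tissue labels, bias field, brain mask) are
  returned.
* `make_toy_atlas()`: equal-volume slabs of the brain ellipsoid along
  the first axis, the first flagged temporal-lobe-like.
* `make_feature_dataset()`: class-conditional normal informative
  features (standardised mean difference `effect_size`, optional
  equicorrelation) among independent noise features, with the shuffled
  informative positions recorded.
* `make_slice_dataset()`: 16×16×4 sequences; class 1 carries a bright
  disk in a fixed quadrant of the middle two slices. Default contrast
  0.6 over a 0.2 background with noise sd 0.05 — strong enough that a
  pixel-mean threshold separates the classes, which is the point: the
  desk-scale question is whether the *network* finds and localises the
  signal, not whether the signal exists.

What passing on phantoms does **not** show: robustness to real scanner
physics (Rician noise, partial volume, motion), to anatomical
variability, or to the failure modes of real registration — the affine
here is exact by construction. The phantoms validate the machinery and
its contracts, not clinical performance; the headline performance
figures reported for this class of pipeline on clinical MRI are neither
reproducible nor contradicted at this scale.

## Problem sizes

The bundled experiments run at desk scale as the package's own choice
of study conditions: 32³-to-48³ phantom grids, cohorts of 8–16
subjects, 40-sequence classification sets, 15–20 training epochs,
10-agent/30-iteration selection runs, and exhaustive oracles at d = 10.
Everything scales up by configuration only.
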