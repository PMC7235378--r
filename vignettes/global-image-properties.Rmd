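---
title: "Global image properties and affective rating prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global image properties and affective rating prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(imaffect)
```

`imaffect` computes thirteen scalar "global" properties of an image —
summaries of colour, spectral composition and spatial structure that are
independent of object content — and relates them to affective ratings
(valence, arousal and similar terms) by cross-validated classification
and by linear regression with model selection. This vignette documents
the models, the tunable parameters and their defaults, the numerical
choices, and what the synthetic test corpus does and does not establish
about real images.

## The thirteen properties

**Colour (`h_mean`, `s_mean`, `v_mean`).** Every pixel is converted from
RGB to HSV (standard hexcone model, hue scaled to [0, 1]) and each
channel is averaged arithmetically over pixels. Hue is *not* averaged
circularly: the conventional rgb2hsv-then-mean procedure treats hue as a
plain number on [0, 1] with a discontinuity at red, and achromatic
pixels contribute hue 0. A circular mean is available
(`hsv_means(img, circular_hue = TRUE)`) as a sensitivity check; for
image sets without a dominant red/magenta split the two differ little.

**Fourier slope and sigma.** The image is converted to grayscale with
BT.601 luma weights (0.299, 0.587, 0.114), mirror-padded to a square
(zero padding would inject spurious high-frequency energy at the seams),
Fourier transformed, and the power spectrum |F|² is averaged over annuli
of integer radius 1 … N/2 cycles/image, excluding DC. The radial
spectrum is then binned into 20 equal intervals of log₁₀ frequency over
the fit range [5, N/4] cycles/image; within each bin the mean log₁₀
power and mean log₁₀ frequency are taken (so an exact power law stays
exactly linear after binning), and an ordinary least-squares line through
the bin means gives the slope. `fourier_sigma` is the mean squared
residual of the binned points about that line, dividing by the number of
non-empty bins. The fit range excludes the lowest frequencies (dominated
by global layout) and the highest octave (pixel-level aliasing); both
ends, and the bin count, are arguments of `fit_loglog()`. Natural scenes
have slopes around −2; the estimator recovers generating exponents in
[−4, 0] monotonically. Because only the fit *range* and binning are
implementation choices, slopes are comparable across implementations in
distribution rather than digit-for-digit.

**Edge density and orientation entropies.** A bank of odd-symmetric
(edge-sensitive) Gabor kernels — 24 orientations over 0–180° (7.5°
steps) × wavelengths {4, 8, 16} px, bandwidth ≈ 1 octave, aspect ratio
0.5 — is applied by FFT-based correlation with circular boundary. Per
pixel, the edge magnitude is the maximal absolute response over the bank
and the orientation is that of the winning filter. Orientations are
stored as the *doubled* filter angle (2θ ∈ [0, 360)): unsigned edge
orientation is 180°-periodic, and doubling maps it onto a full circle so
that a grating occupies one histogram bin regardless of contrast
polarity. `edge_density` is the summed magnitude per pixel × 1000; its
absolute scale depends on the kernel normalization (unit L2 norm here)
and is not comparable across implementations, only across images within
one configuration. `entropy1` is the Shannon entropy (bits) of the
magnitude-weighted orientation histogram with B = 24 bins; B = 24 was
chosen because published means near 4.4 bits exceed log₂ 16, so the bin
count must exceed 16, and 24 (maximum 4.585 bits) accommodates them.
`entropy2` takes the n_top = 10 000 strongest edge elements
(deterministic tie-break by row, then column), accumulates a 24-bin
histogram of pairwise orientation differences over all ordered pairs
within each distance annulus {(0, 20], (20, 40], (40, 80], (80, 160]}
pixels, and returns the mean entropy over annuli with at least 100
pairs. The pair loop is O(n_top²) and implemented in C++; squared
distances between integer pixel coordinates are integers, so the annulus
is a table lookup. A pure-R all-pairs oracle verifies the C++ path on
small maps.

One practical caveat: with an argmax over a quantized bank, oblique
gratings (orientations between filter angles, or at them but with
response nodes) leak some 10–15% of their mass into neighbouring
orientation bins, and line-segment textures of a single orientation
floor around 1–3 bits rather than 0. Axis-aligned gratings reach exactly
one bin. The entropies therefore discriminate *relative* orientation
diversity reliably; their absolute floor is bank-dependent.

**PHOG self-similarity.** The image is reduced to ≤ 100 000 pixels
(bilinear, aspect preserved; smaller images are analyzed at native size
— no upsampling). Signed gradient orientations (0–360°, central
differences with circular wrap, taken from the colour channel with the
maximal gradient magnitude per pixel) are binned into 16 orientation
bins, magnitude-weighted, for the whole image and for the 4 + 16 + 64
sub-rectangles of pyramid levels 1–3. Self-similarity is the median over
the 84 sub-histograms of the histogram intersection Σ min(h, g) with the
ground histogram (median is the PHOG-derivative convention; the mean is
available). Sub-rectangles with no gradient energy count as similarity
0. The circular-wrap gradient makes exactly periodic tilings exactly
self-similar at level 1, which pins down the estimator's upper extreme.

**Symmetry and the response variances Pa/Pf.** Instead of the first
layer of a pretrained convolutional network, the package uses a fixed,
deterministic analytic bank of F = 48 kernels — odd Gabors at 12
orientations × wavelengths {4, 8} px on luminance, plus 12 each on the
R−G and B−Y colour-opponent planes — covering the colour, edge and
texture content that a learned first layer responds to, without a
model-weights dependency. Responses are rectified and max-pooled into an
8 × 8 grid. `sym_lr` compares the pooled grid G with the grid of the
mirrored image, computed as the column-reversed grid with each filter
swapped for its orientation-mirrored partner (θ → 180° − θ, same plane
and wavelength):

sym = 1 − Σ|G − M| / (Σ|G| + Σ|M|),

which is 1 exactly for a mirror-symmetric image; `sym_ud` reverses rows.
A featureless image (zero response everywhere) is defined as symmetry 1
with a warning. For Pa/Pf the grid is normalized per cell to sum 1 over
filters; `var_pa` is the variance over filters of the cell-averaged
response (low = many filters active, "richness") and `var_pf` the mean
over filters of the across-cell variance. Their absolute magnitudes are
implementation-defined (they depend on F, S and the kernel set); ordering
comparisons within one configuration are the meaningful use.

## Classification

`tercile_split()` ranks images by a rating term, labels the lowest and
highest floor(n/3) as the two classes and discards the middle; ties are
broken by stable (rating, id) order, and the labelling is flagged when
more than 5% of labelled items share a boundary value (a tie-dominated
split is still produced, but its accuracy ceiling is lowered by ties).
`cv_svm_accuracy()` runs stratified, seeded 10-fold cross-validation of
an RBF-kernel SVM. Within each fold the features are z-scored using
training-fold statistics only; the kernel width is γ = 1/(d · mean
training variance) with d = 13 (i.e. 1/13 on z-scored data) and C = 1 —
these hyperparameters are recorded in every result and overridable, as
there is no principled default beyond the common 1/d convention. The
report gives the mean fold accuracy, a Student-t 95% CI over folds, and
a two-sided one-sample t against the 50% chance rate with df = 9.
Repeated cross-validation (`repeats`) pools fold accuracies; the default
is a single 10-fold run. `compare_cv()` is the pooled-variance two-sample
t over two fold-accuracy vectors (df = 18 for 10 + 10 folds).

## Regression and model selection

`fit_mlr()` is ordinary least squares with standardized coefficients
βᵢ = bᵢ·sd(xᵢ)/sd(y), adjusted R², and AIC in the
n·ln(RSS/n) + 2(p + 1) convention — only AIC *differences* drive any
decision, so the additive constant is immaterial but recorded.
Per-coefficient p-values are two-sided and reported unadjusted across
the 13 coefficients (the report functions print them with significance
stars; interpret with the usual multiplicity caution). `backward_aic()`
removes, at each step, the single predictor whose removal most decreases
AIC and stops when no removal decreases it; elimination is backward-only
and the path is attached to the result. The reduced model is refitted,
so its βᵢ and R²_adj are recomputed on the retained predictors.
`best_subsets()` enumerates all C(p, k) subsets per size from
precomputed cross-product matrices (guarded at p ≤ 20) and ranks by
R²_adj — for fixed k this equals ranking by R²; the returned membership
matrix feeds `autoplot()` for the standard subset-selection graphic.
`spearman_matrix()` and `compare_feature_distributions()`
(Kruskal–Wallis + pairwise Wilcoxon with Holm correction per feature)
cover the descriptive stages.

## The synthetic corpus

`gen_study()` cycles through seven recipe families — random-phase
power-law noise (exponents spread over [−3.5, −0.5]), gratings, oriented
line-segment textures (uniform and von Mises orientation
distributions), mirror-blended composites, near-uniform colour fields,
periodic tilings (with 0.02 SD pixel noise so the spectrum stays
continuous) and split-content images — sized 128 px by default, each
image seeded deterministically from the study seed. The power-law
generator uses *exact* Fourier amplitudes f^(exponent/2) with
random phases, so its power spectrum (and hence the estimated slope) is
deterministic given the size and exponent; randomness enters the image
domain only. Ratings are an affine map onto the rating scale of
Σ βᵢ zᵢ + ε, where z are the *sample-z-scored measured features* — not
the recipe targets — so the generating coefficients are recoverable
exactly up to noise regardless of generator fidelity, and
`draw_ratings()` re-draws only ε for replicate analyses without
re-extracting features. When `target_r2` is given, the noise SD is set
from the realized signal SD to hit that population R².

What passing tests on this corpus shows: the estimators attain their
analytic extremes and orderings, the classifier is calibrated at chance
under permuted labels and detects planted separations, and the
regression machinery recovers known coefficients at the stated coverage.
What it does not show: agreement with any published per-image value
table. The corpus lacks object content, occlusion, depth-of-field and
photographic tone curves; absolute levels of edge density, Pa/Pf and the
entropies are bank- and normalization-dependent. Comparisons of real
image sets should therefore be made within one `imaffect` configuration.

## Numerical choices and degenerate inputs

* FFT correlation uses circular boundary handling throughout; kernels
  larger than the image are cropped centrally and re-centred to zero DC.
* Constant (featureless) images: zero edge map and edge density 0; the
  orientation histogram and Pa/Pf error out; symmetry is defined as 1
  with a warning; the HOG pyramid errors ("featureless image").
* `second_order_entropy` needs at least 100 pairs in some annulus,
  otherwise "image too sparse".
* Spectral fitting requires a square image of at least 32 px, a spectrum
  spanning ≥ 1.5 decades, and ≥ 8 non-empty bins; exactly periodic
  images can legitimately fail the non-empty-bin requirement because
  their spectrum is discrete.
* Feature extraction over a corpus continues past per-image failures,
  returning NA rows and the failed ids in an attribute.
* All generators take explicit integer seeds (Mersenne–Twister); study
  corpora derive per-image seeds from the study seed.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to make the statistical
assertions sharp while keeping a full run on one CPU in the tens of
minutes: chance calibration at n = 600 features × 20 permutation seeds;
slope recovery on 20 images at 256²; symmetry monotonicity on 10
fixtures × 5 blend weights at 64²; and parameter recovery on a
1000-image study at 128² with features extracted once and 100 rating
replicates. Oracle-equivalence checks (OLS vs normal equations, best
subsets vs brute-force enumeration, C++ pair loop vs all-pairs R,
Holm vs the textbook step-down) run at small sizes where the oracles are
exact.
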