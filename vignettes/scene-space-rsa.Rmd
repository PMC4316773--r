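---
title: "Comparing scene spaces: representational similarity across vision models, brain patterns, and behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing scene spaces: representational similarity across vision models, brain patterns, and behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scenespace)
```

## The problem

How is a visual scene represented — by a pattern of voxel responses in
scene-selective cortex, by a human's judgment of which scenes look alike,
or by the feature vector a computer-vision model assigns to the image?
These three descriptions live in incommensurable spaces, but each induces
the *same kind* of object: an $n \times n$ matrix of pairwise scene
similarities, a *scene space*. Representational similarity analysis (RSA)
compares measurement domains at this second-order level: two methods agree
to the extent that their similarity matrices correlate.

`scenespace` implements that pipeline end to end:

1. **First-order spaces.** For each method, a scenes × features matrix is
   reduced to an $n \times n$ Pearson similarity matrix
   (`pairwise_similarity()`); behavioral rating tables are reduced to a
   matrix of mean log-ratings (`behavioral_matrix()`); trial-level voxel
   data are reduced to one pattern per scene first
   (`build_scene_patterns()`).
2. **Vectorization.** Each matrix's strict upper triangle — $n(n-1)/2$
   pairs, 4950 for 100 scenes — is vectorized in a fixed row-major order
   (`upper_triangle()`) and Fisher-transformed
   ($z = \tfrac12\log\frac{1+r}{1-r}$, `fisher_z()`).
3. **Second-order analysis.** Spaces are correlated across methods with
   Bonferroni-controlled significance (`correlation_table()`), candidate
   models are ranked against a neural target (`rank_models()`), variance is
   partitioned by ordered-block hierarchical regression
   (`hierarchical_regression()`), and differences between model fits are
   tested by a pair-resampling bootstrap (`bootstrap_model_difference()`).

Because real scanner and crowd-sourcing data are large, undeposited, and
noisy, the package ships a first-class synthetic-data module whose ground
truth is known exactly, so every stage can be validated by recovery rather
than by eyeballing.

## Image descriptors

All descriptor code operates on plain numeric arrays in $[0,1]$
(matrices for grayscale, `h × w × 3` for color; luminance weights
0.299/0.587/0.114).

**GIST** (`gist_descriptor()`). A bank of oriented band-pass filters is
built directly in the frequency domain: log-Gaussian radial profiles at 4
center frequencies (0.25, 0.125, 0.0625, 0.03125 cycles/pixel) crossed
with 8 orientation lobes ($\pi$-periodic Gaussians, SD $0.6\pi/8$). Each
of the 32 filters' squared responses is averaged on a 4 × 4 grid, giving
the standard 512-dimensional descriptor. The filters have no DC response,
so a constant image maps to the zero vector — a property the tests pin
down exactly.

**HOG pyramid** (`hog_cell_histograms()`, `hog_block_descriptors()`,
`hog_pyramid()`). Gradients by central differences with replicated
borders; per 8 × 8-pixel cell, magnitude-weighted orientation histograms
with 16 contrast-sensitive bins (360°), 8 contrast-insensitive bins
(180°), and one gradient-energy component. The bin counts were chosen so
that a 90° image rotation permutes bins *exactly* (90° is 4 bins in both
histograms), which turns a qualitative sanity check into a bit-exact test.
Histograms of each spatially overlapping 2 × 2 cell block are stacked and
L2-normalized (a single per-block normalization rather than the fourfold
neighbor scheme of detection-oriented HOG), quantized against a k-means
codebook, and pooled into spatial-pyramid histograms on 1 × 1 (L0),
2 × 2 (L1) and 4 × 4 (L2) grids — level length $k \times$ cells.

**Self-similarity** (`ssim_descriptors()`). At each sample point the
central 5 × 5 patch is correlated (Pearson) with the patch at every
displacement within a 40-pixel radius; the correlation surface is pooled
by maximum into 20 angular × 4 radial log-polar bins and mapped to
$[0,1]$. Points whose window exits the image are skipped and counted;
zero-variance central patches have no defined surface and are flagged
degenerate and excluded. Descriptors are typically quantized into a
300-word codebook.

**Dense local features** (`local_color_features()`). Dense SIFT-style
descriptors without keypoint detection or rotation normalization: 4 × 4
spatial sub-bins × 8 orientation bins over a 16-pixel patch, L2-normalized
with 0.2 clipping, sampled at a stride of 8 px. Variants compute the same
descriptor on the hue channel (`hue_sift`), on R, G and B independently
and concatenated (`rgb_sift`, 384-d), or sample raw local hue values for
quantization into a hue histogram (`hue_hist`). Hue is treated as a linear
channel when differentiated; its circularity is respected in extraction
but not in the gradient, a known simplification.

**Bag of visual words** (`train_codebook()`, `bow_histogram()`). k-means
(10 restarts, seeded, centroid order canonicalized by sorting) with
dictionary sizes typically in \{50, 250, 400, 1000\} for local features
and 300 for self-similarity. Histograms of nearest-centroid assignments
(ties to the lowest index) are L2-normalized; an empty descriptor set
yields the zero vector with a warning rather than an error. When $k$
equals the number of descriptors the exact optimum (each point its own
centroid) is returned directly.

**Geometric classes and attributes.** `geom_descriptor()` block-averages
per-class probability maps (ground/vertical/porous/sky) onto an 8 × 8
grid, 64 values per class, concatenated into `all`.
`reweight_attributes()` implements exponentiated-variance reweighting of
classifier-confidence tables: each attribute column is scaled by
$\exp(v_a)$ where $v_a$ is the variance of its per-category mean scores
(sample variance of the category means — "across scene categories", not
across scenes). The form $\exp(v_a)$ is the plainest reading of
"exponentiated variance"; any base change only rescales columns jointly.

## Neural patterns

`apply_roi_mask()` subsets acquisition volumes to a binary region-of-
interest mask, linearizing voxels in a fixed row-major grid order that is
recorded in the output, and reshapes them by a (scene, repetition,
timepoint) index into a `trial_pattern_array`. `build_scene_patterns()`
averages over repetitions and then over the timepoints whose onset lies in
a closed window — default 6–8 s, which at 2 s sampling captures exactly
the two peak samples of a slow event-related response. Both window
boundaries are closed because "6–8 s" at 2 s spacing naturally includes
both samples. Repetitions lost to dropped trials are averaged over what
remains, with per-scene counts reported. Participant-level similarity
matrices are combined by cell-wise averaging of raw r values
(`average_across_participants()`); averaging on the Fisher scale is
available via `fisher = TRUE`, since the order of those two operations is
a genuine degree of freedom in this literature.

## Behavioral ratings

Ratings arrive in long format: one row per (rater, HIT, scene pair,
response 1–8), where a HIT is an 11-trial task unit containing exactly one
identical-pair catch trial whose correct answer is 8.
`behavioral_matrix()` applies the quality-control cascade:

* any HIT whose catch trial was answered incorrectly is dropped whole;
* raters with at least 2 failed catch trials whose *similarity* responses
  were exclusively 1 or 8 are removed entirely (the exclusivity test is on
  non-catch rows — their wrong catch answers should not rescue them);
* remaining non-catch responses are log-transformed (natural log; any base
  only rescales and cannot change later correlations) and averaged per
  pair. A non-catch response of 8 is kept as a valid maximal rating.

Pairs with no surviving observations become missing cells, which propagate
into pairwise-complete second-order correlations rather than being
imputed. The log transform is motivated by the strong right skew of
similarity judgments — most pairs are simply "different".

## Second-order statistics

`fisher_z()` clamps $|r| = 1$ to $\mathrm{atanh}(1 - 10^{-7})$: identical
synthetic scenes would otherwise produce infinities. Significance in
`correlation_table()` divides $\alpha = 0.05$ either by the number of
scene pairs (4950-style correction) or by a declared family size (for
regression families such as 39 correlations). `hierarchical_regression()`
fits nested OLS models in block order and reports cumulative multiple $R$,
the increment $\Delta R$, and an F test on each $R^2$ increment — the F
test is this package's choice; the increment test behind published tables
of this kind is rarely named. The bootstrap resamples *scene pairs* with
replacement, jointly across target and both models; pairs are the
observations that enter every correlation here, making them the natural
resampling unit (resampling scenes instead is a coherent alternative the
interface could grow). The confidence interval is the percentile interval,
optionally Bonferroni-widened across a declared family; degenerate
resamples are redrawn and counted.

## The synthetic-data module

The generators produce data with the statistical structure the analysis
assumes, with all parameters visible:

* `gen_scene_images()` builds procedural category-structured stimuli: each
  category owns an (orientation, spatial frequency, hue) triple, exemplars
  jitter those parameters and add pixel noise. The default study layout is
  50 categories × 2 exemplars = 100 scenes. Within-category pairs come out
  more similar than between-category pairs under simple descriptors, which
  is all the recovery tests require.
* `gen_attribute_scores()` emulates attribute-classifier confidences as
  category means plus exemplar noise (84 attributes in the learned-
  attribute configuration, 102 in the semantic-attribute one).
* `gen_voxel_patterns()` embeds a target similarity matrix — a weighted
  mixture of model scene spaces — *exactly*: the eigendecomposition square
  root of the target is applied to an orthonormal, mean-centered voxel
  basis (requires `n_voxels >= n_scenes + 1`), so with zero noise the
  recovered scene space equals the target to machine precision. Gaussian
  noise is added per trial; timepoints outside the peak window carry
  attenuated (0.3×) signal. A requested mixture that is not positive
  semidefinite is unrealizable by any pattern set; it is projected to the
  nearest realizable correlation matrix and the adjustment is reported,
  never silent.
* `gen_ratings()` packs roughly 20 observations per pair into 11-trial
  HITs with one catch trial each. Responses discretize the rank-normalized
  true similarity through a shifted truncated Poisson,
  $1 + \min(\mathrm{Pois}(0.04 + 4.5\,s^8), 6)$, whose constants were
  calibrated once against the aggregate skewness (≈ 2.7) reported for this
  kind of judgment — per-pair response distributions are not available to
  calibrate against, so only the pooled shape is matched. Planted "bad"
  raters answer every catch trial incorrectly and press only 1 or 8,
  exactly the profile the exclusion cascade targets.

What the generators deliberately do **not** emulate: hemodynamic response
shapes and scanner noise spectra (trial responses are signal × amplitude +
white noise), retinotopy or any real cortical geometry (voxels are
exchangeable), photographic image statistics (stimuli are gratings with
texture and hue, not scenes), or rater idiosyncrasies beyond the planted
catch-failure profile. Passing recovery tests therefore demonstrates that
the *pipeline arithmetic* is right and identifiable under the assumed
structure — not that the method would survive every pathology of real
data.

## Numerical and design choices

* Similarity matrices are validated symmetric to 1e-10 and Pearson cells
  to $|r| \le 1 + 10^{-12}$; zero-variance feature rows yield missing
  cells plus a warning, never silent zeros.
* The pair ordering everywhere is the row-major strict upper triangle,
  1-based, recorded in file metadata; `reconstruct_similarity()` inverts
  it exactly.
* Nearest-centroid ties break to the lowest centroid index; ranking ties
  break by label order; both are deterministic and reported.
* Every stochastic function takes a `seed` and restores the caller's RNG
  state, so generator calls are reproducible and side-effect-free.
* Recovery simulations in the tests use 40 scenes, 3 orthogonalized model
  spaces with weights 0.6/0.3/0.1, 150 voxels, 6 repetitions, and
  per-trial noise SD 1 (equal to the signal SD; after averaging 6
  repetitions × 2 peak timepoints the effective pattern noise SD is
  ≈ 0.29) — sizes chosen as the smallest at which the second-order
  statistics are comfortably identifiable. The bootstrap calibration null
  uses two models with equal population correlation (0.37) to a common
  target over 780 pairs.

## A worked example

```{r example, eval = FALSE}
spaces <- scenespace:::with_seed(1, {
  L <- 40 * 39 / 2
  M <- qr.Q(qr(matrix(rnorm(L * 3), L, 3))) * sqrt(L) * 0.1
  lapply(1:3, function(j) M[, j])
})
mx <- ground_truth_mixture(spaces, weights = c(0.6, 0.3, 0.1),
                           noise_sd = 1, seed = 2)
tp <- gen_voxel_patterns(mx, n_voxels = 150)
neural <- fisher_space(pairwise_similarity(build_scene_patterns(tp)$patterns))
rank_models(neural, list(m1 = spaces[[1]], m2 = spaces[[2]],
                         m3 = spaces[[3]]))
hierarchical_regression(neural, list(m3 = matrix(spaces[[3]]),
                                     m2 = matrix(spaces[[2]]),
                                     m1 = matrix(spaces[[1]])))
```

## Known limitations

* The GIST bank is a faithful member of the oriented-energy family but not
  a bit-for-bit reimplementation of any published binary; descriptor
  *structure* (length, DC behavior, orientation tuning) is tested, exact
  filter shapes are a design choice.
* Dense SIFT omits Gaussian spatial weighting and bilinear bin
  interpolation; hue gradients ignore circular wraparound.
* The hierarchical F test assumes independent errors across scene pairs,
  which pairs sharing a scene violate; the bootstrap makes the same
  exchangeability assumption. This is inherited from the analysis design
  itself, not introduced by the implementation.
* `behavioral_matrix()` thresholds for whole-rater removal are
  configurable because the verbal rule they encode ("missed a number of
  catch trials … exclusively used only 1 and 8") is qualitative.
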