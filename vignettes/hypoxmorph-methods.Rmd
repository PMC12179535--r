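---
title: "Weakly supervised hypoxia morphology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised hypoxia morphology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Tumor hypoxia — chronic oxygen shortage inside a growing solid tumor — is
usually quantified by assaying the expression of hypoxia-regulated genes, an
extra step outside routine pathology. `hypoxmorph` implements a weakly
supervised alternative: a multiple-instance-learning (MIL) classifier that
learns to recognise hypoxia-associated morphology in ordinary H&E-stained
slide images, using only *sample-level* weak labels derived from a hypoxia
gene signature, and then quantifies what distinguishes the two tissue states
with classical texture and shape morphometry. The package ships a seeded
synthetic-cohort generator with planted, recoverable signal, so every stage
can be exercised and tested end to end on a desktop with no external data.

## Weak labels: the median-split metagene score

Given a genes-by-samples expression matrix and a hypoxia signature gene
list, `buffa_score()` computes, for each sample,

$$ s = \sum_{g \in \text{signature}} \begin{cases} +1 & x_{gs} >
\mathrm{median}_s(x_{g\cdot}) \\ -1 & \text{otherwise,} \end{cases} $$

so with $G$ signature genes the score lies in $[-G, +G]$ and has the parity
of $G$. Ties at the median count as "not above"; this makes the rule
deterministic and is the convention asserted in the tests. Samples with
$s > 0$ are labelled *hypoxic*, the rest *normoxic*; scores above 20 form
the *high* stratum and scores in $(0, 20]$ the *low* stratum used for
per-stratum evaluation. The signature list is an input, not a constant: the
default synthetic signature has 52 genes, the size of the classic hypoxia
metagene, so scores span $[-52, 52]$.

Whether the upstream expression should be normalised before the median
split is deliberately out of scope: the score depends only on per-gene
ranks across the cohort, so any monotone per-gene transformation leaves it
unchanged.

## MIL classification of tile bags

A slide is far too large to classify directly, and the weak label attaches
to the whole sample, not to any particular region. The model therefore
classifies *bags* of tissue tiles:

* **Preprocessing** (`tile_slide()`, `tissue_mask()`, `filter_tiles()`):
  the slide is cut into non-overlapping tiles (default 256 px, 32 px in the
  desk-scale experiments); each tile is converted to grayscale (luminance
  weights 0.2125/0.7154/0.0721) and thresholded by Otsu's method on its own
  histogram, pixels strictly below the threshold counting as tissue; tiles
  whose tissue fraction is not strictly greater than 50% are discarded. The
  boundary is strict at exactly 0.5 because the filter's stated intent is
  to *keep* tiles with more than half tissue. Otsu is computed per tile;
  slide-level thresholding would pool statistics across tiles but is not
  implemented. Constant tiles (pure background) have no Otsu threshold and
  are flagged with tissue fraction 0.
* **Augmentation** (`augment_tile()`): during training each tile receives,
  independently with probability 0.5 each: a rotation by a random multiple
  of 90 degrees (axis-aligned rotations avoid interpolation and padding
  artefacts), horizontal and vertical flips, a hue shift uniform in
  ±0.05 fractional hue, a gamma correction uniform in [0.8, 1.25], and
  additive Gaussian noise with a standard deviation of 5 gray levels —
  mild, label-preserving perturbations.
* **Encoding**: each tile passes through a convolutional backbone; the
  final feature maps are collapsed by global average pooling and linearly
  projected to 512 features per tile. Two backbones are built in: a
  VGG-19-like stack for full-scale use (randomly initialised — no
  pretrained weights are bundled) and a three-block `small_cnn`
  (8/16/32 channels) whose GAP output is projected up to the same 512-long
  contract; the small backbone is what the tests and the synthetic
  experiments use, because a pretrained large encoder adds nothing to a
  synthetic texture task while dominating the runtime.
* **Pooling**: `aggregate_features()` offers element-wise max pooling and
  gated attention pooling (a tanh branch multiplied by a sigmoid gate,
  scored and softmax-normalised over tiles). Attention weights are
  nonnegative, sum to one, and are returned for inspection, giving a
  per-tile importance readout. Both poolings are permutation invariant —
  the defining MIL property, asserted directly in the tests.
* **Head**: the pooled bag feature is rectified, passed through one dense
  layer, and a softmax turns the two logits into class probabilities. The
  rectifier sits *before* the dense layer, a choice that deserves a note
  because the composition softmax–rectifier–dense can be parenthesised two
  ways. Rectifying *after* the dense layer gives the head a genuine flat
  region: when both logits are clamped at zero the output is exactly
  (0.5, 0.5) with zero gradient everywhere, and — worse — whenever exactly
  one logit is clamped, the surviving gradient pushes the logit sum only
  downward, a ratchet that drives SGD into the flat region and keeps it
  there (we observed trained models whose logits separated by 5 units,
  invisible behind the clamp, predicting 0.5 for every sample). Rectifying
  the pooled feature instead keeps the softmax input affine in the
  parameters, which has no such degeneracy; the choice is isolated in
  `classify_bag()`.

Training (`mil_train()`) is plain stochastic gradient descent, one bag per
step, cross-entropy loss; a fresh bag of 20 tiles is drawn per sample at
every epoch (with replacement when a sample has fewer filtered tiles). The
model-level defaults (learning rate 0.0003, 100 epochs, bag size 20) are
the reference training protocol; the pipeline's desk-scale default raises
the learning rate to 0.01 because a cohort of 80 samples seen for 15
epochs gives plain SGD about three orders of magnitude fewer steps than a
thousand-sample, hundred-epoch run, and at 0.0003 the differential
(between-class) component of the gradient cannot accumulate in that
budget. All layers and their gradients are implemented in vectorised R and
verified against finite differences in the test suite.

At inference every filtered tile of a sample forms one bag
(`predict_sample()`); single tiles can be scored as bags of one instance
(`score_tile()`), which is how high-confidence tiles are selected for
morphometry. `activation_map()` produces gradient-weighted class activation
maps from the last convolutional block, normalised to [0, 1] and upsampled
to tile size.

## Evaluation

`stratify_cohort()` draws three independent random 75/25 train/test
splits, stratified by the weak label (stratification is not strictly part
of a plain random split, but at cohort sizes of tens of samples an
unstratified draw can leave a class absent from a side; the splits remain
independent across repetitions). `evaluate_split()` reports AUROC
(rank/trapezoidal convention), accuracy, precision and recall for the full
test set and for the low- and high-stratum subsets, each against all
normoxic test samples; `evaluate_splits()` averages over the repeated
splits, excluding splits where a stratum was empty. Three *independent*
splits, rather than three disjoint folds, are what is implemented and
reported.

## Morphometry

`glcm()` builds the gray-level co-occurrence matrix at 256 gray levels,
distance 1, one direction per angle (0, 45, 90, 135 degrees), normalised to
sum to one. `glcm_features()` computes

* homogeneity $\sum_{ij} P(i,j) / (1 + (i-j)^2)$,
* energy $\sum_{ij} P(i,j)^2$,
* correlation $\sum_{ij} (i-\mu_i)(j-\mu_j) P(i,j) / (\sigma_i \sigma_j)$,

plus contrast and dissimilarity as extras; `texture_features()` averages
the four angles, which also makes the features invariant to 90-degree
image rotation. Correlation is undefined on a constant image (zero
marginal variance) and is returned as `NA` with a flag rather than
imputed. All three features are checked against brute-force double-sum
oracles to 1e-10.

`shape_descriptors()` measures a single-component binary mask: pixel area;
perimeter by Moore-neighbour boundary tracing with Vossepoel–Smeulders
step weights (0.948 axial, 1.340 diagonal) plus a $\pi$ correction for the
half-pixel offset between the pixel-centre chain and the true object
boundary — with it, rasterised disks measure circularity near 1 instead of
well above it; equivalent (area-derived) diameter; major/minor axis
lengths and eccentricity $\sqrt{1 - b^2/a^2}$ from the second central
moments; circularity $4\pi A / P^2$; extent (area over bounding box); and
solidity (area over the rasterised convex hull). "Diameter" in the
descriptor set is read as the equivalent area-derived diameter.

`select_high_confidence()` samples 10 tiles per sample, scores each as a
one-instance bag, and keeps tiles classified with probability above 0.9
for either class; `compare_groups()` then compares any feature between the
predicted-hypoxic and predicted-normoxic groups with a two-sided
Mann–Whitney test (the features are skewed, bounded quantities summarised
by box plots, so a rank test is the natural default; Welch's t is
available behind a flag). Stars follow the convention `***` p < 0.001,
`****` p < 0.0001, on raw per-feature p values without multiplicity
correction — a deliberate mirror of per-feature box-plot annotation, and a
caveat for any reading of many features at once.

## The synthetic cohort: what is planted and what is not

`synth_config()` fixes every generator knob; all outputs are pure
functions of it.

* **Slides**: a near-white background (gray level 242) with one elliptical
  tissue region covering ≈55% of the slide (so at least 30% stays
  background). Tissue is smoothed pink noise — an H&E-like hue — whose
  Gaussian correlation length is the class's `texture_granularity`
  (defaults: 2.5 px normoxic, 1.0 px hypoxic, so hypoxic tissue is
  finer-grained and measures *lower* homogeneity, energy and correlation,
  matching the direction of the reported biology). About a quarter of the
  tissue area is brighter "stromal gap" blobs: they keep pure-tissue tiles
  bimodal in grayscale, which is what per-tile Otsu segmentation of
  stained tissue implicitly relies on, and they set the within-tissue
  tissue-fraction near 0.75 rather than hovering at the 0.5 filter
  boundary.
* **Nuclei** are dark ellipses with class- and cell-type-specific axis
  lengths (defaults: epithelial 9×9 px normoxic vs 16×8 px hypoxic —
  planted axis ratios 1 vs 2; macrophages 12×7 vs 10×9, i.e. *rounder*
  under hypoxia). A single per-cell size factor (s.d. 8%) jitters both
  axes, preserving the planted ratio. Centres are stamped at integer pixel
  positions: a digital disk at an integer centre is exactly 4-fold
  symmetric, so a planted ratio of 1 measures a moment eccentricity of
  exactly 0, while subpixel centres would add spurious eccentricity of
  order 0.1–0.2. Nuclei are convex by construction, so planted solidity is
  identically 1 — solidity differences in real cells are not emulated.
* **Expression**: per-gene log-normal (log-s.d. 0.5, heavy-tailed and
  positive like RNA-seq magnitudes; the exact distribution is irrelevant
  to a rank-based score). Hypoxic samples shift their signature genes up
  by `signature_shift` (default 2.5, i.e. 5 within-class s.d.) scaled by a
  per-sample intensity drawn uniform on [0.35, 1]: hypoxia is graded in
  real cohorts, and the graded shift produces a continuum of positive
  scores that populates both the low and the high stratum while keeping
  the weak labels essentially error-free. Setting `intensity_range =
  c(1, 1)` plants the full shift in every hypoxic sample.
* **Annotated tiles** carry the same tissue texture plus non-overlapping
  nucleus masks with per-cell planted axes recorded, emitted as
  integer-labelled masks plus a CSV index (not any particular annotation
  XML dialect).

What passing tests on this cohort do *not* show: the generator has no
stain variation, no pen marks or folds, no nucleus clumping or overlap, no
pyramidal slide formats, and its two classes differ by construction in a
single texture scale — so planted-signal recovery demonstrates that the
pipeline's machinery (weak labelling, bag construction, optimisation,
evaluation, morphometry) is correct, not that the classifier would reach
any particular accuracy on clinical slides.

## Problem sizes and determinism

The end-to-end experiments run at deliberately small scale: 40 samples per
class, 256×256 px slides, 32×32 px tiles (about 30 tissue tiles per
slide), the small backbone, bags of 20 tiles, 15 epochs, three stratified
splits plus one label-permutation null (evaluated on the predictions
pooled over the three permuted splits, which puts the chance-level AUROC
band at roughly ±0.15). Unit tests use smaller cohorts still. Every stage
takes an explicit seed, and regeneration from the same configuration is
bit-identical; the permutation null and the planted-signal experiment
share one generated cohort via `prepare_cohort()`.

## Known limitations

* The VGG-19-like backbone is provided untrained; nothing in the package
  downloads weights.
* Per-tile Otsu thresholding assumes a locally bimodal histogram; tiles of
  pure uniform tissue in real slides can read arbitrary fractions.
* The comparison tables use raw per-feature p values; treat stars across
  many features as descriptive, not confirmatory.
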