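# hypoxmorph

Weakly supervised detection of hypoxia-associated morphology in
H&E-stained histology images, with downstream texture and shape
morphometry — implemented end to end in R and exercised on seeded
synthetic cohorts with planted, recoverable signal.

## The problem

Tumor hypoxia (chronic oxygen shortage inside a solid tumor) changes both
gene expression and tissue morphology, and matters clinically: hypoxic
tumor regions resist radiotherapy. Hypoxia is normally quantified with an
expression assay — scoring a hypoxia gene signature — which is an extra
test outside routine pathology. The idea implemented here is to learn
those morphological correlates directly from routine H&E slides, using the
expression-derived score only as a *weak, sample-level label*, so that
once trained the model needs nothing but the slide image.

For whom: computational-pathology researchers who want a tested,
dependency-light reference implementation of this weak-label pipeline —
scoring, tiling, multiple-instance learning (MIL), and morphometry — that
runs and validates on a laptop without any external data.

## The method

1. **Weak labels** (`buffa_score`): for signature genes $g$ and samples
   $s$, the hypoxia score is the median-split metagene sum
   $\;score_s = \sum_g \pm 1\;$ (+1 iff $x_{gs}$ is strictly above the
   cohort median of gene $g$). Samples with positive scores are labelled
   hypoxic; scores in (0, 20] form the *low* and above 20 the *high*
   stratum.
2. **Tiling** (`tile_slide`, `tissue_mask`, `filter_tiles`): slides are
   cut into tiles; per-tile Otsu thresholding on the grayscale histogram
   separates stained tissue (below threshold) from background; tiles with
   more than 50% tissue are kept.
3. **MIL classification** (`mil_model`, `mil_train`, `predict_sample`):
   bags of 20 tiles per sample are encoded by a convolutional backbone
   into 512-long tile features (global average pooling + linear
   projection), aggregated by element-wise max pooling or gated attention
   pooling $\;z = \sum_i a_i F_i,\; a_i \ge 0,\; \sum a_i = 1$, and
   classified by a rectified-feature softmax head
   $L = \mathrm{softmax}(\mathrm{ReLU}(z) W_1 + b_1)$. Training is plain
   SGD with cross-entropy, fresh bags every epoch. All layers and
   gradients are hand-written vectorised R, verified against finite
   differences.
4. **Evaluation** (`stratify_cohort`, `evaluate_split`): three stratified
   75/25 train/test splits; AUROC/accuracy/precision/recall overall and
   per stratum; a label-permutation null pins the chance level.
5. **Morphometry** (`glcm`, `texture_features`, `shape_descriptors`): on
   high-confidence tiles (single-tile score > 0.9), gray-level
   co-occurrence texture features at distance 1 averaged over the four
   axis directions — homogeneity $\sum P(i,j)/(1+(i-j)^2)$, energy
   $\sum P(i,j)^2$, correlation
   $\sum (i-\mu_i)(j-\mu_j)P(i,j)/(\sigma_i\sigma_j)$; on annotated cell
   masks, area, perimeter, equivalent diameter, eccentricity
   $\sqrt{1-b^2/a^2}$, circularity $4\pi A/P^2$, extent and solidity;
   groups compared by two-sided Mann–Whitney tests with `***`/`****`
   stars at p < 0.001 / p < 0.0001.
6. **Synthetic cohorts** (`synth_config`, `generate_slides`,
   `generate_expression`, `generate_annotated_tiles`): seeded generators
   plant class-specific texture granularity, a signature expression
   shift, and nuclear ellipse geometry, so every downstream statistic has
   a known ground truth. See the methods vignette
   (`vignettes/hypoxmorph-methods.Rmd`) for what is and is not emulated.

## Worked example

```r
library(hypoxmorph)

cfg <- synth_config(seed = 11, n_samples_per_class = 40,
                    slide_size_px = c(256, 256), tile_size_px = 32)
cohort <- prepare_cohort(cfg)          # slides + tiling + weak labels
table(cohort$scores$stratum)
#>     high      low normoxic
#>       38        2       40

bundle <- run_pipeline(cfg, seed = 101, epochs = 15, cohort = cohort,
                       n_annotated_per_class = 25)
sapply(bundle$split_metrics, function(m) m$auroc[1])
#> [1] 1 1 1
```

The weak labels recover the planted expression shift perfectly (38 + 2
hypoxic vs 40 normoxic), and each of the three stratified test splits
ranks every held-out hypoxic sample above every normoxic one (AUROC 1):
the planted texture difference is fully recovered from the weak labels
alone. The same pipeline with `shuffle_labels = TRUE` gives a pooled
test AUROC of 0.51 — chance level, confirming the signal is not leakage.
Cell-shape comparisons from the same bundle:

```r
subset(bundle$shape_comparisons, cell_type == "epithelial",
       c(feature, mean_hypoxic, mean_normoxic, p_value, stars))
#>       feature mean_hypoxic mean_normoxic  p_value stars
#>          area      100.820        64.164 1.85e-32  ****
#>  eccentricity        0.868         0.000 1.30e-41  ****
#>   circularity        0.829         0.977 1.21e-35  ****
#>      solidity        1.000         1.000       NA
#>        extent        0.731         0.792 5.36e-08  ****
```

The planted epithelial axis ratio (2 under hypoxia vs 1) is read back by
the moment-based eccentricity (0.868 measured vs 0.866 analytic; 0.000 vs
0), with the circularity and extent shifts that follow geometrically;
macrophages show the opposite planted pattern (rounder under hypoxia,
eccentricity 0.390 vs 0.809). Synthetic nuclei are convex, so solidity is
identically 1 by construction and its comparison is reported without a p
value. Texture comparisons on high-confidence tiles
(`select_high_confidence`, single-tile score > 0.9) need a model trained
to convergence — the 15-epoch demo model ranks perfectly but is not yet
confident at tile level; the test suite exercises that path with a
longer-trained model.

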