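---
title: "Methods: ranking tissue regions for targeted spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ranking tissue regions for targeted spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sequencing a full spatial-transcriptomics slide is expensive; a practical
alternative is to sequence only a handful of ~500 x 500 um regions of
interest (ROIs) chosen from the routine H&E image. `roirank` ranks candidate
ROIs two ways:

* **Regional diversity** — discovery mode: find regions likely to capture
  heterogeneous expression.
* **Targeted conditional** — hypothesis mode: find regions matching a text
  prompt (e.g. "tumor") and rich in a target cell type.

Both scores blend a *visual* arm computed from patch embeddings of the H&E
image with a *cellular* arm computed from a nucleus-level cell-type map, and
both are validated against ground-truth rankings derived from spot-level
expression on the same window lattice.

## The window lattice

The cropped tissue (the bounding box of in-tissue spots padded by one spot
diameter) is tiled into non-overlapping 224 x 224 px patches; edge tiles are
padded with white pixels, and the padding participates in patch statistics,
so edge patches tend to be filtered as background. At 0.274 um/px a patch
spans ~61 um and an 8 x 8-patch window ~491 um — about 0.6% of a 6.5 mm
square capture area, and a close match to the field of view of targeted
spatial platforms. Windows slide with a default stride of one patch; a
105 x 105-patch slide yields (105 - 7)^2 = 9,604 overlapping candidates.

Patches pass a three-stage filter cascade, in order and short-circuiting:

1. *Prefilter* (before embedding): exactly all-white (every value 255) or
   all-black (every value 0).
2. *Tier 1* (background): mean grayscale >= 235 **and** population std < 20;
   optionally also >= 85% of pixels with all RGB channels >= 230. The color
   check defaults **off** and is exposed as a flag, since it is described as
   an optional confirmation step.
3. *Tier 2* (low variance): remaining patches with std < 10.

Grayscale is ITU-R 601 luma (`round(0.299 R + 0.587 G + 0.114 B)`) and the
standard deviation is the population form (divide by N); neither convention
changes which of the tested thresholds fire on the constructed patches in
the test suite, and the flagged fraction moves by well under five
percentage points when the mean threshold varies over 230-240 and the std
threshold over 15-25.

## Scores

**Visual diversity.** All retained-patch embeddings are reduced to 30
dimensions with UMAP (`n_neighbors = 15`, `min_dist = 0.1`, seed 42), fit
globally; each window's score is the median pairwise Euclidean distance
among its retained patches' reduced vectors. Windows with fewer than two
retained patches score zero. UMAP initializes from PCA when the input has
at least 30 columns and from a seeded random layout otherwise (PCA cannot
produce more components than input columns).

**Cellular diversity.** Nuclei are assigned to patches by centroid
containment. Per window, the Shannon entropy (base 2) of the cell-type
proportions is multiplied by `log(1 + N)` (natural log — the entropy's base
is stated, the density weight's is not, so the conventional natural log is
used); windows with fewer than 10 cells score zero. The class universe is
all predicted labels; classes such as "negative control" can be excluded
via `entropy_exclude`.

**Text similarity.** Cosine similarity between the prompt embedding and
each retained patch's embedding, aggregated as the linear-interpolation
0.9-quantile over the window, clipped below at zero, then raised to the
power 10. Clipping precedes the exponent so that negative similarities
cannot alias to large positive scores under even powers. The order of
operations is quantile, clip, exponent, then global min-max.

**Cell abundance.** `log(1 + count)` of target-class nuclei in the window.

Each pair of components is min-max normalized across all windows of a run
(a constant component normalizes to all zeros) and blended as
`w * (visual or text) + (1 - w) * (cellular or count)` with default
`w = 0.5`; `w = 1` and `w = 0` reproduce the encoder-only and
classifier-only baselines, and `weight_sweep()` re-blends cached components
over a weight grid.

**Selection.** Ranked windows (descending score, ties by ascending anchor
row then column) pass a greedy spacing filter. The default `any_axis` rule
accepts a candidate separated from every accepted window by at least the
window size along rows *or* columns, which is exactly the zero-overlap
condition for axis-aligned squares. The literal reading of the spacing
sentence — separation along *both* axes — is stricter than non-overlap
(it also forbids abutting windows that share an edge-aligned band) and is
kept as `both_axes` for users who want sparser spatial sampling.

## Nucleus annotation

Zero-shot labels come from the argmax cosine similarity between each
nucleus embedding and the text embeddings of the label names (ties break to
the lowest class index). Expert refinement is modeled as an active-learning
session: per cycle, a batch of unannotated nuclei is chosen
(uncertainty-first by default — smallest top-two probability margin, with
ties rounded at 1e-9 and broken at random so floating-point noise cannot
bias selection), labeled by the annotator, and the gradient-boosted
classifier (100 trees, depth 6, learning rate 0.3, softmax-probability
objective — stated defaults, no tuning) is retrained on the *cumulative*
annotation set and reapplied to all nuclei. Annotations are never
discarded; training requires at least two classes and errors otherwise
rather than silently fitting a one-class model. Zero-shot labels seed only
the display and the uncertainty ordering, never the training set — the
training set is expert annotations alone.

The simulated annotator stands in for the pathologist: it returns planted
true labels with a configurable mislabel rate and an optional per-cycle
class focus. A focused annotator reproduces the documented transient-dip
behavior (early single-class batches can temporarily unbalance the
training set); the suite asserts only that the final accuracy is at least
the zero-shot accuracy, since the dip's depth is scenario-specific.

## Ground truth from expression

Counts are CP10K log-normalized per spot (`ln(1 + 10^4 c / total)`); spots
with zero totals are dropped with a warning. Each spot's per-type score is
the mean normalized expression of the type's marker genes (matched
case-insensitively; absent genes dropped per type with a warning); the spot
takes the argmax type if that score reaches 1.0 normalized units, else
"Unclassified". The 1.0 threshold is applied on the log-normalized scale,
since the procedure describes the threshold after the log transform.
Unclassified spots are excluded from both the entropy proportions and the
spot count N (they mark classification failure, not a biological type);
a flag can retain them as a category. Ground-truth windows use the same
lattice and stride as the model run, so model and ground-truth rankings
share one window ID set. Diversity ground truth uses the same
entropy-times-`log(1+N)` form with a 10-spot minimum; tumor ground truth is
the raw count of tumor-classified spots.

## Evaluation

* **Spearman's rho** over the anchors common to both rankings, computed
  from scores with average ranks for ties (not from arbitrary list
  positions).
* **Overlap@K**: percentage of identical anchors shared by the two top-K
  sets. "Overlap@10%" uses `K = round(0.10 x N_common)`; the reference
  count is the common window set, configurable.
* **Set IoU@K**: the two top-K sets are rasterized into their 8 x 8 patch
  cells and compared as unions.
* **Bootstrap CI**: the common anchors are resampled with replacement
  (default 1,000 replicates, seeded); rho is recomputed per replicate and
  the 2.5/97.5 percentiles reported. Degenerate replicates with zero rank
  variance on either side are skipped and counted.
* **Random baseline**: uniform random scores on the ground-truth window
  set; the expected Overlap@K is the hypergeometric mean `100 K / N`.

## The synthetic slide generator

The generator emulates the study conditions end to end so that every stage
runs offline. A scenario is a rectangular zone layout over the patch grid;
each zone carries a kind (tissue/background), a patch-embedding class, a
nucleus density, and a cell-type mixture.

* **Patch images** follow an exact block model: each 224-px patch is an
  8 x 8 lattice of constant 28-px blocks drawn from the zone's palette
  (near-white grays 244-252 for background, an H&E-like mix of dark
  nuclear, eosin-pink and pale lumen tones for tissue). Because blocks are
  equal-sized and constant, patch-level pixel statistics equal the
  statistics of the 64 block values, so a 105 x 105-patch slide needs no
  gigapixel array; `realize_patch()` expands any patch to its full
  224 x 224 x 3 pixels, and the realized statistics match the stored ones
  exactly.
* **Embeddings** come from the synthetic backend: class prototypes are rows
  of a seeded random orthonormal basis (so between-class cosine is exactly
  0 and within-class exactly 1 at zero noise), items add isotropic Gaussian
  noise, text maps to the exact prototype. Default dimension 32; the
  1024/512 dimensions quoted for production encoders are the plug-in
  adapters' contract.
* **Nuclei** are placed uniformly within patches at the zone's density
  (Poisson per patch) with types drawn from the zone mixture; their true
  labels are kept hidden from the pipeline and used only for planted ground
  truth and accuracy logging.
* **Spot counts** are negative-binomial. Defaults: a 2 x 2 spot lattice per
  patch, `base_mu = 5` per gene (about 100 total counts per spot on the
  ~20-gene panel — the depth regime of near-single-cell binned spots),
  dispersion 0.1 (UMI-dominated, near-Poisson noise), and a 6x mean
  up-shift of the spot's matching-type marker genes. At these settings
  marker classification recovers planted spot types at ~94% even when the
  effect size is reduced to 3x. Earlier drafts of the generator used a
  much shallower depth (~20 counts/spot) and heavy dispersion (0.5), under
  which no classifier can recover types reliably on the log-CP10K scale —
  the revised defaults are the realistic regime, not a tuned one.
* **Planted rankings** are computed from the true nucleus labels with the
  same entropy/count formulas used for expression-derived ground truth.
  This makes the targeted score with true labels and `w = 0` a strictly
  monotone transform of the planted tumor ranking, so its recovery is
  exact (`rho = 1`) — a structural identity, not a statistical outcome.

### Presets

* `margin` — tumor-dominant side (85/5/10 tumor/immune/stromal), stromal
  side (8/12/80), and a mixed margin band (45/20/35); noiseless embeddings.
  Windows straddling the margin have the highest planted diversity.
* `prostate_like` — dense epithelial gland background with two
  tumor-dominant nodules.
* `lung_like` — sparse cellularity and near-white background zones that
  exercise the tier-1 filter.
* `complementary` — four vertical strips A/B/C/D designed so the two score
  arms carry complementary information: the A|B interface separates two
  mixtures through *distinct* patch-embedding classes while A's and B's
  tumor/immune labels carry 50% flip noise (visual arm informative,
  cellular arm degraded); C and D share one embedding class but differ in
  their low-noise stromal fraction (cellular arm informative, visual arm
  blind). On this scenario the `w = 0.5` blend matches or beats both pure
  arms — the inverted-U weight profile — because each pure arm is blind to
  one interface. The noise rates were chosen from this construction, not
  adjusted afterwards.

### What the generator does and does not emulate

It reproduces the *quantities the method consumes*: patch statistics with
realistic background/tissue contrast, embedding geometry with tunable
class separation, spatially structured cell-type mixtures, and
marker-structured overdispersed counts. It does not attempt realistic H&E
texture, nucleus morphology, spatial expression gradients within zones,
segmentation errors, or batch effects — so passing recovery tests shows
the ranking machinery is correct and well-calibrated, not that any
particular encoder or segmenter performs well on real slides.

## Problem sizes and numerical choices

The test suite uses 10-40-patch grids (hundreds to ~1,100 windows) and
36-patch grids over 5 seeds for the weight-profile check; the chance-level
check uses the full 105 x 105 grid (9,604 windows, 100 random replicates),
which completes in seconds because the ground truth is planted rather than
recomputed per replicate. Quantiles use R's default linear interpolation
(type 7). Min-max normalization maps a constant score vector to all zeros.
Ties in every argmax break to the lowest class index; ties in rankings
break by ascending anchor row then column, so all orderings are total and
reproducible. All randomness flows from explicit integer seeds; seeded
helpers save and restore the caller's RNG state.

## Known limitations

Annotation variability is modeled only as an i.i.d. mislabel rate — no
inter-observer structure. The expression ground truth inherits the marker
sets' biases; a type with a single marker gene (e.g. stromal/COL1A1) is
noticeably noisier than one with four. The `both_axes` spacing rule and
the inclusion of unclassified spots are available but non-default, and the
two-step "gate by targeted score, re-rank by diversity" recipe is a
composition of existing operations rather than a separate code path:
threshold `score_targeted()`'s ranking, subset the window set, and re-rank
with `score_diversity()`'s combined score.
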