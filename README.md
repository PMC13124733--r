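# roirank

Rank candidate regions of interest (ROIs) on H&E whole-slide images for
targeted spatial-transcriptomics sequencing.

Sequencing an entire slide is costly; most of a section carries redundant
or uninformative signal. `roirank` scores every ~491 × 491 µm window of a
slide (an 8 × 8 lattice of 224-px patches at 0.274 µm/px) so that a small
set of non-overlapping, high-value regions can be sent for sequencing.
It implements two complementary rankings, each a weighted blend of two
min–max-normalized components:

**Regional diversity** (discovery):

$$S_\text{Diversity} = w \cdot \text{Score}_\text{visual} + (1-w)\cdot \text{Score}_\text{cellular}$$

* *visual*: median pairwise Euclidean distance between the window's patch
  embeddings after a global 30-dimensional UMAP reduction;
* *cellular*: Shannon entropy (base 2) of the window's nucleus cell-type
  proportions, weighted by `log(1 + N)`, zero below 10 cells.

**Targeted conditional** (hypothesis-driven, e.g. prompt `"tumor"`):

$$S_\text{Targeted} = w \cdot \text{Score}_\text{VLM} + (1-w)\cdot \text{Score}_\text{count}$$

* *VLM*: 0.9-quantile of patch–prompt cosine similarities, clipped at 0 and
  raised to the 10th power;
* *count*: `log(1 + #target-class nuclei)` in the window.

The cellular side comes from a nucleus classifier bootstrapped zero-shot
from image–text embeddings and refined by an active-learning loop
(gradient-boosted trees retrained on cumulative annotations; a simulated
annotator stands in for the pathologist). Rankings are validated against
ground truth built from spot-level expression: CP10K-log-normalized counts,
marker-gene spot classification (threshold 1.0, else "Unclassified"), and
the same window lattice — compared with Spearman's ρ (bootstrap CIs),
Overlap@K, and Set IoU@K.

A fully seeded synthetic slide generator (patch textures, embeddings,
nuclei, negative-binomial spot counts with planted marker structure, and
planted ground-truth rankings) makes the entire pipeline runnable and
testable offline; a pluggable backend contract accepts real pathology
vision–language encoders.

## Worked example

Score a synthetic slide with a tumor/stroma margin and compare against the
planted ground truth:

```r
library(roirank)

scn   <- scenario_preset("margin", n = 30, seed = 7)
slide <- make_slide(scn)
slide
#> <synthetic_slide> 30 x 30 patches, 10792 nuclei, 3600 spots

nuclei <- slide$nuclei
nuclei$info$label <- slide$truth_labels      # or zero_shot_label() / active_learning_session()

cfg     <- score_config()                    # w = 0.5, UMAP 30-d, stride 1
reduced <- reduce_embeddings(slide$patch_emb, cfg)
scored  <- score_diversity(slide$grid, reduced, nuclei, cfg)
rk <- region_ranking(data.frame(anchor_row = scored$anchor_row,
                                anchor_col = scored$anchor_col,
                                score = scored$combined), "diversity")
head(as.data.frame(rk), 3)
#>   anchor_row anchor_col     score
#> 1         22         12 0.9608879
#> 2         21         12 0.9587001
#> 3         20         12 0.9563400

greedy_nonoverlap_select(rk, k = 3)[, c("anchor_row", "anchor_col")]
#>    anchor_row anchor_col
#> 1          22         12
#> 4           4         12
#> 39         13         12

evaluate_ranking(rk, slide$planted$diversity, ks = c(10, 50),
                 n_boot = 1000, seed = 1)
#> <eval_report> rho = 0.998 [0.996, 0.999] over 529 common windows
#>   Overlap@K (%): 10: 80.0, 50: 92.0
#>   Set IoU@K:     10: 0.867, 50: 0.976
```

The top-ranked windows line up on the planted tumor/stroma margin (anchor
columns near 12 on a 30-patch grid with the margin band at columns 13–16):
windows straddling the interface mix zone textures and cell types, which
maximizes both score components. ρ = 0.998 against the planted ranking
says the blended score orders essentially all 529 windows as the planted
cell-type entropy does; the greedy step then returns spatially disjoint
picks (anchors at least 8 patches apart on some axis).

The nuclei HDF5 layout (group `SegmentationNode`) stores parallel datasets
`embedding` (D × N), `nucleus_id`, `centroid_row`, `centroid_col`,
`detection_prob`, `label`. Marker sets ship as editable JSON under
`inst/extdata/markers/` (`lung_colon`, `prostate`, `kidney`).

A thin CLI wraps the main entry points:

```sh
Rscript inst/cli/roirank.R simulate --preset margin --n 40 --seed 42 --out bundle/
Rscript inst/cli/roirank.R validate --bundle bundle/
Rscript inst/cli/roirank.R score    --bundle bundle/ --mode diversity --w 0.5 --out ranking.csv
Rscript inst/cli/roirank.R evaluate --model ranking.csv --gt bundle/planted_diversity.csv
```

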