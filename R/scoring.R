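# ROI window generation and scoring.
#
# Candidate ROIs are 8x8-patch sliding windows over the lattice. Two scores
# are computed per window, each a weighted blend of two min-max-normalized
# components:
#   diversity:  w * visual (median pairwise distance of UMAP-reduced patch
#               embeddings) + (1-w) * cellular (Shannon entropy of the cell-
#               type mix, weighted by log(1+N), zero below 10 cells)
#   targeted:   w * text-prompt similarity (0.9-quantile of patch cosine
#               similarities, clipped at 0, raised to an exponent)
#               + (1-w) * log(1 + target-cell count)
# Ranked windows are then thinned with a greedy non-overlapping selection.

#' Scoring configuration
#'
#' @param w Blend weight in \[0, 1\] between the visual/text component
#'   (weight `w`) and the cellular component (weight `1 - w`). Default 0.5.
#' @param umap_dims Reduced dimensionality for visual diversity (default 30).
#' @param umap_neighbors,umap_min_dist,umap_seed UMAP parameters
#'   (defaults 15, 0.1, 42).
#' @param quantile Aggregation quantile for text similarity (default 0.9).
#' @param exponent Contrast exponent applied to the aggregated text
#'   similarity (default 10).
#' @param min_cells Windows with fewer cells (or ground-truth spots) than
#'   this score zero on the cellular component (default 10).
#' @param stride Window anchor stride in patches (default 1).
#' @param window Window side in patches (default 8).
#' @param prompt Text prompt for targeted scoring.
#' @param entropy_exclude Character vector of classes excluded from the
#'   entropy universe (e.g. `"negative control"`); empty by default.
#' @return A named list of class `score_config`.
#' @export
score_config <- function(w = 0.5, umap_dims = 30L, umap_neighbors = 15L,
                         umap_min_dist = 0.1, umap_seed = 42L,
                         quantile = 0.9, exponent = 10, min_cells = 10L,
                         stride = 1L, window = 8L, prompt = "",
                         entropy_exclude = character()) {
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  if (quantile < 0 || quantile > 1) stop("quantile must lie in [0, 1]")
  if (stride < 1 || window < 1) stop("stride and window must be >= 1")
  structure(list(w = w, umap_dims = as.integer(umap_dims),
                 umap_neighbors = as.integer(umap_neighbors),
                 umap_min_dist = umap_min_dist, umap_seed = as.integer(umap_seed),
                 quantile = quantile, exponent = exponent,
                 min_cells = as.integer(min_cells), stride = as.integer(stride),
                 window = as.integer(window), prompt = prompt,
                 entropy_exclude = entropy_exclude),
            class = "score_config")
}

#' Physical geometry of the patch/window lattice
#'
#' @param patch_px Patch side in pixels (default 224).
#' @param microns_per_pixel Imaging resolution (default 0.274 um/px).
#' @param window Window side in patches (default 8).
#' @param capture_mm Side of the square capture area in mm (default 6.5).
#' @return List: `patch_um` (patch span, um), `window_um` (window span, um),
#'   `capture_fraction_pct` (window area as % of the capture area).
#' @export
roi_geometry <- function(patch_px = 224, microns_per_pixel = 0.274,
                         window = 8, capture_mm = 6.5) {
  patch_um <- patch_px * microns_per_pixel
  window_um <- window * patch_um
  list(patch_um = patch_um, window_um = window_um,
       capture_fraction_pct = 100 * (window_um / 1000)^2 / capture_mm^2)
}

#' Generate sliding ROI windows over a patch grid
#'
#' Anchors lie on the lattice `{0, stride, 2*stride, ...}` in both axes,
#' restricted to anchors whose full `window x window` extent fits inside the
#' grid.
#'
#' @param grid A [build_grid()] lattice (at least `window` patches a side).
#' @param cfg A [score_config()] (stride and window size).
#' @return Data frame with columns `anchor_row`, `anchor_col` (0-based patch
#'   units), in row-major anchor order.
#' @export
sliding_windows <- function(grid, cfg = score_config()) {
  w <- cfg$window
  if (grid$n_rows < w || grid$n_cols < w)
    stop("grid (", grid$n_rows, "x", grid$n_cols,
         ") is smaller than the ", w, "x", w, " window")
  rows <- seq(0L, grid$n_rows - w, by = cfg$stride)
  cols <- seq(0L, grid$n_cols - w, by = cfg$stride)
  g <- expand.grid(anchor_col = cols, anchor_row = rows)
  data.frame(anchor_row = g$anchor_row, anchor_col = g$anchor_col)
}

#' Reduce patch embeddings with UMAP
#'
#' Fit globally on all retained patches, reducing to `umap_dims` dimensions
#' (default 30); reproducible for a fixed seed.
#'
#' @param emb `N x D` embedding matrix (retained patches).
#' @param cfg A [score_config()].
#' @return `N x umap_dims` matrix of reduced coordinates.
#' @export
reduce_embeddings <- function(emb, cfg = score_config()) {
  if (nrow(emb) < cfg$umap_neighbors + 1)
    stop("too few patches (", nrow(emb), ") for n_neighbors = ",
         cfg$umap_neighbors, "; lower umap_neighbors")
  old <- .Random.seed_save()
  set.seed(cfg$umap_seed)
  # PCA init needs at least umap_dims input columns; fall back to a seeded
  # random init for narrower embeddings
  init <- if (ncol(emb) >= cfg$umap_dims) "pca" else "rand"
  red <- suppressWarnings(uwot::umap(
    emb, n_components = cfg$umap_dims, n_neighbors = cfg$umap_neighbors,
    min_dist = cfg$umap_min_dist, n_threads = 1, n_sgd_threads = 1,
    init = init, verbose = FALSE))
  .Random.seed_restore(old)
  red
}

# ---- per-window primitives --------------------------------------------------

#' Median pairwise distance of a window's reduced embeddings
#'
#' @param vectors Matrix of reduced embeddings for the window's retained
#'   patches (possibly 0 or 1 rows).
#' @return Median over all pairwise Euclidean distances; 0 for fewer than 2
#'   rows.
#' @export
visual_diversity <- function(vectors) {
  if (is.null(vectors) || nrow(vectors) < 2) return(0)
  median(stats::dist(vectors))
}

#' Density-weighted Shannon entropy of a cell-type composition
#'
#' `H = -sum_i p_i log2(p_i)` over the type proportions, multiplied by
#' `log(1 + N)` (natural log). Compositions with fewer than `min_cells`
#' members score zero.
#'
#' @param counts Named or unnamed non-negative vector of per-type counts.
#' @param min_cells Minimum total count (default 10).
#' @return Non-negative score.
#' @export
cellular_entropy <- function(counts, min_cells = 10L) {
  N <- sum(counts)
  if (N < min_cells) return(0)
  p <- counts[counts > 0] / N
  H <- -sum(p * log2(p))
  H * log(1 + N)
}

#' Min-max normalize scores across all windows
#'
#' @param x Numeric vector.
#' @return `(x - min) / (max - min)`; all zeros when the scores are constant.
#' @export
minmax_normalize <- function(x) {
  if (length(x) == 0) return(numeric())
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(rep(0, length(x)))
  (x - lo) / (hi - lo)
}

#' Blend two normalized diversity components
#'
#' @param visual,cellular Normalized component scores in \[0, 1\].
#' @param w Weight on the visual component.
#' @return `w * visual + (1 - w) * cellular`.
#' @export
diversity_score <- function(visual, cellular, w = 0.5) {
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  w * visual + (1 - w) * cellular
}

#' Blend two normalized targeted components
#'
#' @param vlm,count Normalized component scores in \[0, 1\].
#' @param w Weight on the text-similarity component.
#' @return `w * vlm + (1 - w) * count`.
#' @export
targeted_score <- function(vlm, count, w = 0.5) {
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  w * vlm + (1 - w) * count
}

#' Aggregate patch-prompt similarities into a window text score
#'
#' Takes the linear-interpolation `quantile` of the per-patch cosine
#' similarities, clips negative values to 0, and raises the result to
#' `exponent`. Applied before global min-max normalization.
#'
#' @param sims Numeric vector of per-patch cosine similarities for the
#'   window's retained patches (possibly empty).
#' @param quantile Aggregation quantile (default 0.9).
#' @param exponent Contrast exponent (default 10).
#' @return Non-negative score; 0 for an empty window.
#' @export
text_similarity_score <- function(sims, quantile = 0.9, exponent = 10) {
  if (length(sims) == 0) return(0)
  q <- as.numeric(stats::quantile(sims, probs = quantile, type = 7))
  max(q, 0)^exponent
}

#' Log-abundance of target cells in a window
#'
#' @param count Number of nuclei of the target class in the window.
#' @return `log(1 + count)` (natural log).
#' @export
cell_abundance_score <- function(count) log(1 + count)

# ---- window aggregation machinery -------------------------------------------

# Summed-area table of a matrix; entry [i+1, j+1] = sum of M[1:i, 1:j].
summed_area <- function(M) {
  S <- matrix(0, nrow(M) + 1L, ncol(M) + 1L)
  S[-1L, -1L] <- t(apply(apply(M, 2, cumsum), 1, cumsum))
  S
}

# Window sums of a per-patch matrix over anchors (0-based), window w.
window_sums <- function(M, anchor_row, anchor_col, w) {
  S <- summed_area(M)
  i0 <- anchor_row + 1L; j0 <- anchor_col + 1L
  S[cbind(i0 + w, j0 + w)] - S[cbind(i0, j0 + w)] -
    S[cbind(i0 + w, j0)] + S[cbind(i0, j0)]
}

# Per-patch counts by class: matrix list, one n_rows x n_cols matrix per class.
patch_class_counts <- function(grid, patch_row, patch_col, class, classes) {
  keep <- patch_row >= 0 & patch_row < grid$n_rows &
          patch_col >= 0 & patch_col < grid$n_cols & !is.na(class)
  lapply(classes, function(cl) {
    sel <- keep & class == cl
    M <- matrix(0L, grid$n_rows, grid$n_cols)
    if (any(sel)) {
      tab <- table(factor(patch_row[sel], levels = 0:(grid$n_rows - 1L)),
                   factor(patch_col[sel], levels = 0:(grid$n_cols - 1L)))
      M <- matrix(as.integer(tab), grid$n_rows, grid$n_cols)
    }
    M
  })
}

# Patch coordinates of nuclei centroids (cropped-frame px -> patch units).
nuclei_patch_coords <- function(nuclei, patch_px = 224L) {
  list(row = nuclei$info$centroid_row %/% patch_px,
       col = nuclei$info$centroid_col %/% patch_px)
}

# Per-window class-count matrix (windows x classes) for labeled points.
window_class_counts <- function(grid, windows, patch_row, patch_col, class,
                                classes, w) {
  per_class <- patch_class_counts(grid, patch_row, patch_col, class, classes)
  out <- vapply(per_class, function(M)
    window_sums(M, windows$anchor_row, windows$anchor_col, w),
    numeric(nrow(windows)))
  matrix(out, nrow = nrow(windows), dimnames = list(NULL, classes))
}

# Entropy-based window scores from a windows x classes count matrix.
window_entropy_scores <- function(counts, min_n) {
  N <- rowSums(counts)
  P <- counts / pmax(N, 1)
  H <- -rowSums(ifelse(P > 0, P * log2(P), 0))
  ifelse(N < min_n, 0, H * log(1 + N))
}

# ---- pipeline wrappers ------------------------------------------------------

# Map from patch (row, col) to row index in a retained-only matrix; NA where
# not retained.
retained_index_matrix <- function(grid, retained) {
  idx <- rep(NA_integer_, grid$n_rows * grid$n_cols)
  idx[which(retained)] <- seq_len(sum(retained))
  # patches data frame is row-major: fill by row
  matrix(idx, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
}

#' Score all windows with the Regional Diversity Score
#'
#' Computes the visual component (median pairwise distance of the reduced
#' embeddings of the window's retained patches) and the cellular component
#' (density-weighted entropy of the labeled nuclei falling inside the
#' window), min-max normalizes each across windows, and blends them with
#' weight `w`.
#'
#' @param grid A filtered [build_grid()] lattice.
#' @param reduced Reduced embeddings ([reduce_embeddings()]), one row per
#'   retained patch in row-major patch order.
#' @param nuclei A labeled [nuclei_table()].
#' @param cfg A [score_config()].
#' @return Data frame: anchors, `score_visual`, `score_cellular` (both
#'   normalized), `combined`.
#' @export
score_diversity <- function(grid, reduced, nuclei, cfg = score_config()) {
  windows <- sliding_windows(grid, cfg)
  retained <- retained_patches(grid)
  idx_mat <- retained_index_matrix(grid, retained)
  w <- cfg$window
  visual_raw <- vapply(seq_len(nrow(windows)), function(i) {
    sub <- idx_mat[windows$anchor_row[i] + seq_len(w),
                   windows$anchor_col[i] + seq_len(w)]
    rows <- sub[!is.na(sub)]
    if (length(rows) < 2) 0 else visual_diversity(reduced[rows, , drop = FALSE])
  }, numeric(1))

  pc <- nuclei_patch_coords(nuclei, grid$patch_px)
  classes <- setdiff(sort(unique(nuclei$info$label)), cfg$entropy_exclude)
  cellular_raw <- if (length(classes) == 0) rep(0, nrow(windows)) else {
    lab <- nuclei$info$label
    lab[lab %in% cfg$entropy_exclude] <- NA
    counts <- window_class_counts(grid, windows, pc$row, pc$col, lab, classes, w)
    window_entropy_scores(counts, cfg$min_cells)
  }

  windows$score_visual <- minmax_normalize(visual_raw)
  windows$score_cellular <- minmax_normalize(cellular_raw)
  windows$combined <- diversity_score(windows$score_visual,
                                      windows$score_cellular, cfg$w)
  windows
}

#' Score all windows with the Targeted Conditional Score
#'
#' Computes the text-similarity component (0.9-quantile of patch-prompt
#' cosine similarities, clipped at 0, exponent-sharpened) and the target-
#' cell abundance component (`log(1 + count)`), min-max normalizes each
#' across windows, and blends them with weight `w`.
#'
#' @param grid A filtered [build_grid()] lattice.
#' @param patch_emb Embedding matrix of the retained patches (row-major
#'   patch order).
#' @param text_emb Text embedding of the prompt (same dimension).
#' @param nuclei A labeled [nuclei_table()].
#' @param target_class Cell-type label whose abundance is scored.
#' @param cfg A [score_config()].
#' @return Data frame: anchors, `score_vlm`, `score_count` (both
#'   normalized), `combined`.
#' @export
score_targeted <- function(grid, patch_emb, text_emb, nuclei, target_class,
                           cfg = score_config()) {
  if (!target_class %in% nuclei$info$label)
    stop("target_class '", target_class, "' not present among nucleus labels")
  windows <- sliding_windows(grid, cfg)
  retained <- retained_patches(grid)
  idx_mat <- retained_index_matrix(grid, retained)
  w <- cfg$window
  sims <- cosine_sim_rows(patch_emb, text_emb)
  vlm_raw <- vapply(seq_len(nrow(windows)), function(i) {
    sub <- idx_mat[windows$anchor_row[i] + seq_len(w),
                   windows$anchor_col[i] + seq_len(w)]
    rows <- sub[!is.na(sub)]
    text_similarity_score(sims[rows], cfg$quantile, cfg$exponent)
  }, numeric(1))

  pc <- nuclei_patch_coords(nuclei, grid$patch_px)
  counts <- window_class_counts(grid, windows, pc$row, pc$col,
                                nuclei$info$label, target_class, w)
  count_raw <- cell_abundance_score(counts[, 1])

  windows$score_vlm <- minmax_normalize(vlm_raw)
  windows$score_count <- minmax_normalize(count_raw)
  windows$combined <- targeted_score(windows$score_vlm, windows$score_count,
                                     cfg$w)
  windows
}

#' Greedy non-overlapping selection of top windows
#'
#' Scans windows in ranking order and accepts a candidate only if it is
#' spatially compatible with every previously accepted window. Under
#' `"any_axis"` (default) the candidate must be separated by at least the
#' window size along rows *or* columns (`|drow| >= window || |dcol| >=
#' window`), which guarantees zero patch overlap. `"both_axes"` requires
#' separation along both axes, a stricter spacing rule.
#'
#' @param ranking A [region_ranking()] (descending score, ties by ascending
#'   anchor row then column).
#' @param k Number of windows to select (>= 1).
#' @param mode `"any_axis"` or `"both_axes"`.
#' @param window Window side in patches (default 8).
#' @return The selected rows of `ranking`, in acceptance order.
#' @export
greedy_nonoverlap_select <- function(ranking, k, mode = c("any_axis", "both_axes"),
                                     window = 8L) {
  mode <- match.arg(mode)
  if (k < 1) stop("k must be >= 1")
  acc_r <- integer(); acc_c <- integer(); keep <- integer()
  for (i in seq_len(nrow(ranking))) {
    r <- ranking$anchor_row[i]; c <- ranking$anchor_col[i]
    ok <- if (length(acc_r) == 0) TRUE else {
      dr <- abs(acc_r - r) >= window
      dc <- abs(acc_c - c) >= window
      if (mode == "any_axis") all(dr | dc) else all(dr & dc)
    }
    if (ok) {
      keep <- c(keep, i); acc_r <- c(acc_r, r); acc_c <- c(acc_c, c)
      if (length(keep) == k) break
    }
  }
  ranking[keep, , drop = FALSE]
}

#' Re-rank cached components over a grid of blend weights
#'
#' Reuses component scores computed once, producing one ranking per weight.
#'
#' @param windows A scored window data frame ([score_diversity()] or
#'   [score_targeted()] output).
#' @param w_grid Numeric vector of weights in \[0, 1\] (non-empty).
#' @param method Ranking label prefix.
#' @return Named list of [region_ranking()]s, one per weight.
#' @export
weight_sweep <- function(windows, w_grid, method = "sweep") {
  if (length(w_grid) == 0) stop("empty weight grid")
  comp <- if ("score_visual" %in% names(windows))
    list(a = windows$score_visual, b = windows$score_cellular)
  else list(a = windows$score_vlm, b = windows$score_count)
  out <- lapply(w_grid, function(w) {
    df <- data.frame(anchor_row = windows$anchor_row,
                     anchor_col = windows$anchor_col,
                     score = diversity_score(comp$a, comp$b, w))
    region_ranking(df, method = sprintf("%s_w%.1f", method, w))
  })
  names(out) <- sprintf("w%.1f", w_grid)
  out
}
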