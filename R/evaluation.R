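# Ranking comparison: Spearman correlation over the common window set,
# Overlap@K, Set IoU@K, bootstrap confidence intervals, and the
# random-score baseline.

#' Construct a region ranking
#'
#' An ordered list of window anchors with scores, comparable across
#' methods. Rows are sorted by descending score, ties broken by ascending
#' anchor row then column; anchors must be unique.
#'
#' @param df Data frame with `anchor_row`, `anchor_col`, `score` (plus any
#'   component-score columns, which are kept).
#' @param method Label identifying the producing method.
#' @return `df` sorted, with class `region_ranking` and attribute `method`.
#' @export
region_ranking <- function(df, method = "unknown") {
  stopifnot(all(c("anchor_row", "anchor_col", "score") %in% names(df)))
  if (anyDuplicated(df[, c("anchor_row", "anchor_col")]))
    stop("ranking anchors must be unique")
  ord <- order(-df$score, df$anchor_row, df$anchor_col)
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("region_ranking", "data.frame")
  attr(out, "method") <- method
  out
}

anchor_key <- function(x) paste(x$anchor_row, x$anchor_col, sep = "_")

#' Spearman correlation over the common window set
#'
#' Restricts both rankings to their anchor intersection and computes the
#' Spearman rank correlation of the scores there (tied scores receive
#' average ranks).
#'
#' @param model,gt [region_ranking()]s.
#' @return Correlation in \[-1, 1\].
#' @export
spearman_common <- function(model, gt) {
  km <- anchor_key(model); kg <- anchor_key(gt)
  common <- intersect(km, kg)
  if (length(common) < 3)
    stop("need at least 3 common anchors, found ", length(common))
  ms <- model$score[match(common, km)]
  gs <- gt$score[match(common, kg)]
  cor(ms, gs, method = "spearman")
}

#' Overlap@K between two rankings
#'
#' Percentage of the top-K anchor sets shared between model and ground
#' truth; windows match only on identical anchor coordinates.
#'
#' @param model,gt [region_ranking()]s with at least `K` entries each.
#' @param K Top-list depth.
#' @return Percentage in \[0, 100\].
#' @export
overlap_at_k <- function(model, gt, K) {
  if (K < 1) stop("K must be >= 1")
  if (nrow(model) < K || nrow(gt) < K)
    stop("K = ", K, " exceeds a ranking's length")
  tm <- anchor_key(model[seq_len(K), ])
  tg <- anchor_key(gt[seq_len(K), ])
  100 * length(intersect(tm, tg)) / K
}

# Patch-cell ids covered by the union of a set of windows.
rasterize_windows <- function(anchors_row, anchors_col, window, n_cols_hint = NULL) {
  offs <- expand.grid(dr = 0:(window - 1L), dc = 0:(window - 1L))
  cells <- unlist(lapply(seq_along(anchors_row), function(i)
    paste(anchors_row[i] + offs$dr, anchors_col[i] + offs$dc, sep = "_")))
  unique(cells)
}

#' Set IoU@K between two rankings
#'
#' Rasterizes each ranking's top-K windows into their patch cells and
#' returns the intersection-over-union of the two cell unions.
#'
#' @param model,gt [region_ranking()]s with at least `K` entries each.
#' @param K Top-list depth.
#' @param window Window side in patches (default 8).
#' @return IoU in \[0, 1\].
#' @export
set_iou_at_k <- function(model, gt, K, window = 8L) {
  if (K < 1) stop("K must be >= 1")
  if (nrow(model) < K || nrow(gt) < K)
    stop("K = ", K, " exceeds a ranking's length")
  cm <- rasterize_windows(model$anchor_row[seq_len(K)],
                          model$anchor_col[seq_len(K)], window)
  cg <- rasterize_windows(gt$anchor_row[seq_len(K)],
                          gt$anchor_col[seq_len(K)], window)
  length(intersect(cm, cg)) / length(union(cm, cg))
}

#' Bootstrap confidence interval for the Spearman correlation
#'
#' Resamples the common anchors with replacement `n_boot` times,
#' recomputing the correlation on each resampled multiset (average ranks
#' for ties), and returns the 2.5/97.5 percentiles. Degenerate replicates
#' (zero rank variance on either side) are skipped and counted.
#'
#' @param model,gt [region_ranking()]s with >= 10 common anchors.
#' @param n_boot Number of bootstrap samples (default 1000).
#' @param seed Integer seed.
#' @return List: `lo`, `hi`, `n_skipped`, `rho` (point estimate).
#' @export
bootstrap_rho_ci <- function(model, gt, n_boot = 1000L, seed = 1L) {
  km <- anchor_key(model); kg <- anchor_key(gt)
  common <- intersect(km, kg)
  if (length(common) < 10)
    stop("need at least 10 common anchors, found ", length(common))
  ms <- model$score[match(common, km)]
  gs <- gt$score[match(common, kg)]
  old <- .Random.seed_save()
  set.seed(seed)
  reps <- numeric(n_boot); skipped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(length(common), replace = TRUE)
    a <- ms[idx]; g <- gs[idx]
    if (length(unique(a)) < 2 || length(unique(g)) < 2) {
      skipped <- skipped + 1L
      reps[b] <- NA_real_
    } else reps[b] <- cor(a, g, method = "spearman")
  }
  .Random.seed_restore(old)
  qs <- quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(lo = qs[1], hi = qs[2], n_skipped = skipped,
       rho = cor(ms, gs, method = "spearman"))
}

#' Random-ranking baseline
#'
#' For each seed, ranks the ground-truth windows by independent uniform
#' random scores and evaluates against the ground truth; reports the means
#' of Spearman's correlation and Overlap@`round(frac_k * N)` across seeds.
#'
#' @param gt A [region_ranking()] with >= 100 windows.
#' @param frac_k Top fraction for the overlap (default 0.1).
#' @param n_seeds Number of random replicates (default 100).
#' @param seed Base seed; replicate `s` uses `seed + s`.
#' @return List: `mean_rho`, `mean_overlap`, `rho` and `overlap` per-seed
#'   vectors, `K`, `n`.
#' @export
random_baseline <- function(gt, frac_k = 0.1, n_seeds = 100L, seed = 0L) {
  n <- nrow(gt)
  if (n < 100) stop("ground-truth ranking must have at least 100 windows")
  K <- max(1L, as.integer(round(frac_k * n)))
  rho <- numeric(n_seeds); ov <- numeric(n_seeds)
  base <- data.frame(anchor_row = gt$anchor_row, anchor_col = gt$anchor_col)
  old <- .Random.seed_save()
  for (s in seq_len(n_seeds)) {
    set.seed(seed + s)
    base$score <- runif(n)
    rnd <- region_ranking(base, method = "random")
    rho[s] <- spearman_common(rnd, gt)
    ov[s] <- overlap_at_k(rnd, gt, K)
  }
  .Random.seed_restore(old)
  list(mean_rho = mean(rho), mean_overlap = mean(ov),
       rho = rho, overlap = ov, K = K, n = n)
}

#' Full evaluation report comparing two rankings
#'
#' @param model,gt [region_ranking()]s.
#' @param ks Integer vector of K values for Overlap@K and Set IoU@K.
#' @param overlap_frac Additional overlap at `round(frac * N_common)`.
#' @param n_boot Bootstrap samples for the correlation CI.
#' @param seed Integer seed for the bootstrap.
#' @param window Window side in patches.
#' @return List of class `eval_report`: `rho`, `rho_ci`, `overlap_at`,
#'   `set_iou_at`, `overlap_frac_pct`, `n_common`.
#' @export
evaluate_ranking <- function(model, gt, ks = c(10L, 50L, 100L),
                             overlap_frac = 0.1, n_boot = 1000L, seed = 1L,
                             window = 8L) {
  n_common <- length(intersect(anchor_key(model), anchor_key(gt)))
  ci <- bootstrap_rho_ci(model, gt, n_boot = n_boot, seed = seed)
  Kf <- max(1L, round(overlap_frac * n_common))
  structure(list(
    rho = ci$rho, rho_ci = c(ci$lo, ci$hi),
    overlap_at = setNames(vapply(ks, overlap_at_k, numeric(1),
                                 model = model, gt = gt), ks),
    set_iou_at = setNames(vapply(ks, set_iou_at_k, numeric(1),
                                 model = model, gt = gt, window = window), ks),
    overlap_frac_pct = overlap_at_k(model, gt, Kf),
    n_common = n_common), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> rho = %.3f [%.3f, %.3f] over %d common windows\n",
              x$rho, x$rho_ci[1], x$rho_ci[2], x$n_common))
  cat("  Overlap@K (%):", paste(sprintf("%s: %.1f", names(x$overlap_at),
                                        x$overlap_at), collapse = ", "), "\n")
  cat("  Set IoU@K:    ", paste(sprintf("%s: %.3f", names(x$set_iou_at),
                                        x$set_iou_at), collapse = ", "), "\n")
  invisible(x)
}
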