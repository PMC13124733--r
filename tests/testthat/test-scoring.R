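test_that("window geometry matches the assay's physical dimensions", {
  g <- roi_geometry()
  expect_equal(round(g$patch_um), 61)
  expect_equal(g$patch_um, 224 * 0.274)
  expect_equal(g$window_um, 8 * 61.376)
  expect_equal(round(g$capture_fraction_pct, 1), 0.6)
})

test_that("sliding windows enumerate stride-aligned anchors with full coverage", {
  expect_identical(nrow(sliding_windows(build_grid(10 * 224, 10 * 224))), 9L)
  w1 <- sliding_windows(build_grid(8 * 224, 8 * 224))
  expect_identical(nrow(w1), 1L)
  expect_identical(c(w1$anchor_row, w1$anchor_col), c(0L, 0L))
  expect_identical(nrow(sliding_windows(build_grid(105 * 224, 105 * 224))), 9604L)
  # stride-aligned count formula
  g <- build_grid(20 * 224, 17 * 224)
  for (s in 1:3) {
    w <- sliding_windows(g, score_config(stride = s))
    expect_identical(nrow(w),
                     as.integer(ceiling((20 - 7) / s) * ceiling((17 - 7) / s)))
    expect_true(all(w$anchor_row %% s == 0 & w$anchor_col %% s == 0))
    expect_true(all(w$anchor_row + 8 <= 20 & w$anchor_col + 8 <= 17))
  }
  expect_error(sliding_windows(build_grid(7 * 224, 10 * 224)), "smaller")
})

test_that("UMAP reduction is seeded, 30-dimensional and separates planted clusters", {
  be <- synthetic_backend(c("a", "b"), dim = 16, seed = 2, sigma = 0.05)
  cls <- rep(c("a", "b"), each = 60)
  emb <- embed_items(be, cls, seed = 3)
  r1 <- reduce_embeddings(emb)
  r2 <- reduce_embeddings(emb)
  expect_identical(r1, r2)
  expect_identical(ncol(r1), 30L)
  same <- as.matrix(dist(r1))[cls == "a", cls == "a"]
  cross <- as.matrix(dist(r1))[cls == "a", cls == "b"]
  expect_gt(mean(cross), mean(same[upper.tri(same)]))
  expect_error(reduce_embeddings(emb[1:10, ]), "umap_neighbors")
})

test_that("visual diversity equals the brute-force pairwise median oracle", {
  # hand example: distances {5, 10, 5} -> median 5
  M <- rbind(c(0, 0), c(3, 4), c(6, 8))
  expect_equal(visual_diversity(M), 5)
  expect_equal(visual_diversity(rbind(c(1, 1), c(1, 1), c(1, 1))), 0)
  expect_equal(visual_diversity(M[1, , drop = FALSE]), 0)
  set.seed(13)
  for (i in 1:50) {
    n <- sample(2:20, 1)
    X <- matrix(rnorm(n * 5), n, 5)
    expect_equal(visual_diversity(X), brute_median_pairdist(X),
                 tolerance = 1e-12)
  }
})

test_that("cellular entropy follows the closed form with the min-cell rule", {
  expect_equal(cellular_entropy(c(16, 0, 0)), 0)           # one type: H = 0
  expect_equal(cellular_entropy(c(3, 3, 3)), 0)            # 9 cells < 10
  expect_equal(cellular_entropy(c(8, 8)), log(17))         # H = 1 bit
  expect_equal(cellular_entropy(c(8, 8)), 2.8332, tolerance = 1e-4)
  # bounds: 0 <= H <= log2(k); score scales by log(1 + N)
  set.seed(3)
  for (i in 1:30) {
    k <- sample(2:5, 1)
    cnt <- rpois(k, 20)
    if (sum(cnt) < 10) next
    H <- cellular_entropy(cnt, min_cells = 10) / log(1 + sum(cnt))
    expect_gte(H, 0)
    expect_lte(H, log2(k) + 1e-12)
  }
})

test_that("min-max normalization maps to [0,1] and zeros constant input", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(minmax_normalize(c(0, 10)), c(0, 1))
})

test_that("score blends are exact at the endpoints and monotone in components", {
  expect_equal(diversity_score(0.4, 0.8, 0.5), 0.6)
  expect_equal(diversity_score(0.4, 0.8, 1), 0.4)
  expect_equal(diversity_score(0.4, 0.8, 0), 0.8)
  expect_equal(targeted_score(1.0, 0.0, 0.5), 0.5)
  expect_error(diversity_score(0.5, 0.5, 1.2), "\\[0, 1\\]")
  expect_error(targeted_score(0.5, 0.5, -0.1), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:20) {
    w <- runif(1)
    a <- runif(2); b <- runif(1)
    expect_gte(diversity_score(max(a), b, w), diversity_score(min(a), b, w))
    expect_gte(targeted_score(b, max(a), w), targeted_score(b, min(a), w))
  }
})

test_that("text similarity aggregates by quantile, clips, then sharpens", {
  expect_equal(text_similarity_score(rep(1, 10)), 1)
  expect_equal(text_similarity_score(rep(0.5, 10), exponent = 10), 0.5^10)
  expect_equal(text_similarity_score(rep(0.5, 10), exponent = 10),
               9.766e-4, tolerance = 1e-4)
  expect_equal(text_similarity_score(c(-0.5, -0.1, -0.9)), 0)
  expect_equal(text_similarity_score(numeric()), 0)
  # linear-interpolation quantile
  expect_equal(text_similarity_score(c(0, 1), quantile = 0.9, exponent = 1), 0.9)
})

test_that("cell abundance is the log-count and is monotone", {
  expect_equal(cell_abundance_score(0), 0)
  expect_equal(cell_abundance_score(99), log(100))
  expect_equal(cell_abundance_score(99), 4.6052, tolerance = 1e-4)
  cnt <- sort(sample(0:500, 20))
  expect_true(all(diff(cell_abundance_score(cnt)) >= 0))
})

test_that("greedy selection accepts abutting windows and rejects overlaps", {
  rk <- region_ranking(data.frame(
    anchor_row = c(0, 0, 0), anchor_col = c(0, 8, 4),
    score = c(3, 2, 1)), "t")
  sel <- greedy_nonoverlap_select(rk, k = 3)
  expect_identical(nrow(sel), 2L)
  expect_setequal(sel$anchor_col, c(0, 8))
  # the rejected window overlaps the first in 8 x 4 patches
  ov <- sum(brute_raster(0, 0, 8, 20) & brute_raster(0, 4, 8, 20))
  expect_identical(ov, 32L)
  # k = 1 returns the single top window
  sel1 <- greedy_nonoverlap_select(rk, k = 1)
  expect_identical(c(sel1$anchor_row, sel1$anchor_col), c(0, 0))
  expect_error(greedy_nonoverlap_select(rk, k = 0), ">= 1")
  # both_axes is stricter: the abutting pair is rejected too
  selb <- greedy_nonoverlap_select(rk, k = 3, mode = "both_axes")
  expect_identical(nrow(selb), 1L)
})

test_that("any-axis greedy selection yields zero patch overlap on random fields", {
  set.seed(77)
  n_side <- 12L
  anchors <- expand.grid(anchor_col = 0:(n_side - 8), anchor_row = 0:(n_side - 8))
  worst <- 0L
  for (rep in 1:1000) {
    df <- data.frame(anchor_row = anchors$anchor_row,
                     anchor_col = anchors$anchor_col,
                     score = runif(nrow(anchors)))
    sel <- greedy_nonoverlap_select(region_ranking(df, "r"), k = 4)
    covered <- brute_raster(sel$anchor_row[1], sel$anchor_col[1], 8, n_side + 8)
    for (i in seq_len(nrow(sel))[-1]) {
      nxt <- brute_raster(sel$anchor_row[i], sel$anchor_col[i], 8, n_side + 8)
      worst <- max(worst, sum(covered & nxt))
      covered <- covered | nxt
    }
  }
  expect_identical(worst, 0L)
})

test_that("weight sweeps reuse components and reproduce the pure baselines", {
  slide <- make_slide(scenario_preset("margin", n = 12, seed = 21))
  nuclei <- slide$nuclei
  nuclei$info$label <- slide$truth_labels
  cfg <- score_config(umap_neighbors = 10)
  reduced <- reduce_embeddings(slide$patch_emb, cfg)
  scored <- score_diversity(slide$grid, reduced, nuclei, cfg)
  sweep <- weight_sweep(scored, seq(0, 1, by = 0.2))
  expect_length(sweep, 6L)
  # w = 1 ranking equals ranking by the visual component alone
  pure_vis <- region_ranking(data.frame(anchor_row = scored$anchor_row,
                                        anchor_col = scored$anchor_col,
                                        score = scored$score_visual), "v")
  expect_identical(sweep[["w1.0"]][, c("anchor_row", "anchor_col")],
                   pure_vis[, c("anchor_row", "anchor_col")])
  # identical weights give identical rankings on repeated calls
  sweep2 <- weight_sweep(scored, c(0.4, 0.4))
  expect_identical(sweep2[[1]]$score, sweep2[[2]]$score)
  expect_error(weight_sweep(scored, numeric()), "empty")
})

test_that("stride-2 scoring ranks windows consistently with stride 1", {
  scn <- scenario_preset("margin", n = 24, seed = 33)
  r1 <- recovery_experiment(scn, score_config(stride = 1), mode = "diversity",
                            labels_from = "true")
  r2 <- recovery_experiment(scn, score_config(stride = 2), mode = "diversity",
                            labels_from = "true")
  expect_lt(abs(r1$rho - r2$rho), 0.05)
})
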