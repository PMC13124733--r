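toy_counts <- function() {
  # genes x spots with controlled totals
  genes <- c("EPCAM", "CEACAM5", "PTPRC", "CD3D", "CD8A", "MS4A1",
             "COL1A1", "PECAM1", "FILLER01")
  m <- Matrix::Matrix(0, length(genes), 4, sparse = TRUE,
                      dimnames = list(genes, paste0("s", 1:4)))
  m["EPCAM", 1] <- 40; m["CEACAM5", 1] <- 40; m["FILLER01", 1] <- 20
  m["PTPRC", 2] <- 60; m["CD3D", 2] <- 30;  m["FILLER01", 2] <- 10
  m["FILLER01", 3] <- 100
  m["COL1A1", 4] <- 90; m["FILLER01", 4] <- 10
  methods::as(m, "CsparseMatrix")
}

test_that("CP10K log normalization matches closed forms", {
  genes <- c("G1", "G2")
  m <- Matrix::Matrix(c(2, 19998, 0, 10000), 2, 2, sparse = TRUE,
                      dimnames = list(genes, c("a", "b")))
  nm <- normalize_counts(m)
  # spot total 20,000, count 2 -> CP10K 1 -> ln 2
  expect_equal(nm["G1", "a"], log(2), tolerance = 1e-12)
  # zero count stays zero
  expect_equal(nm["G1", "b"], 0)
  # single expressed gene at total 10,000 -> ln(10001)
  expect_equal(nm["G2", "b"], log(10001), tolerance = 1e-12)
  expect_equal(nm["G2", "b"], 9.2104, tolerance = 1e-4)
  # zero-total spots are dropped with a warning
  m0 <- cbind(m, Matrix::Matrix(0, 2, 1, sparse = TRUE,
                                dimnames = list(genes, "empty")))
  expect_warning(nm0 <- normalize_counts(m0), "zero total")
  expect_identical(ncol(nm0), 2L)
  expect_error(normalize_counts(m[, integer(0)]), "empty")
})

test_that("spot classification assigns argmax above threshold, else Unclassified", {
  markers <- load_marker_set("lung_colon")
  cls <- classify_spots(normalize_counts(toy_counts()), markers)
  expect_identical(cls$type, c("tumor", "immune", "Unclassified", "stromal"))
  # argmax with scores below 1.0 is Unclassified regardless of ranking
  expect_lt(max(cls[3, grep("^score_", names(cls))]), 1.0)
  # exact tie breaks to the first type in marker-set order
  tie <- Matrix::Matrix(c(5000, 5000, 0), 3, 1, sparse = TRUE,
                        dimnames = list(c("EPCAM", "PTPRC", "COL1A1"), "t"))
  mk <- marker_set(list(tumor = "EPCAM", immune = "PTPRC"))
  cl <- classify_spots(normalize_counts(tie), mk)
  expect_identical(cl$type, "tumor")
  # absent markers are dropped per type with a warning; all-absent is an error
  expect_warning(classify_spots(normalize_counts(toy_counts()),
                                marker_set(list(tumor = c("EPCAM", "NOPE"),
                                                immune = "PTPRC"))),
                 "absent")
  expect_error(suppressWarnings(classify_spots(
    normalize_counts(toy_counts()),
    marker_set(list(ghost = "NOTAGENE", immune = "PTPRC")))), "ghost")
})

test_that("classification is invariant to gene/spot order and count scaling", {
  markers <- load_marker_set("lung_colon")
  m <- toy_counts()
  ref <- classify_spots(normalize_counts(m), markers)
  perm <- classify_spots(normalize_counts(m[sample(nrow(m)), sample(ncol(m))]),
                         markers)
  expect_identical(perm$type[match(ref$spot_id, perm$spot_id)], ref$type)
  # doubling all counts in one spot preserves its CP10K profile
  m2 <- m
  m2[, 1] <- m2[, 1] * 2
  expect_identical(classify_spots(normalize_counts(m2), markers)$type[1],
                   ref$type[1])
})

test_that("spot-to-patch assignment is half-open and drops out-of-crop spots", {
  crop <- structure(list(row_min = 100L, row_max = 100L + 448L,
                         col_min = 50L, col_max = 50L + 448L),
                    class = "crop_bounds")
  spots <- spot_table(c("a", "b", "c"),
                      c(100, 100 + 224, 10),
                      c(50, 50 + 223, 60), c(TRUE, TRUE, TRUE))
  asg <- assign_spots_to_patches(spots, crop)
  expect_identical(nrow(asg), 2L)
  expect_identical(asg$patch_row, c(0L, 1L))
  expect_identical(asg$patch_col, c(0L, 0L))
})

test_that("ground-truth window scores match the closed-form entropy oracle", {
  grid <- build_grid(8 * 224, 8 * 224)   # single window at (0,0)
  mk_classified <- function(types) data.frame(
    spot_id = seq_along(types), patch_row = 0L, patch_col = 0L, type = types)
  cfg <- score_config()
  # 20 spots, one type -> 0
  r <- gt_diversity_ranking(mk_classified(rep("tumor", 20)), grid, cfg)
  expect_equal(r$score, 0)
  # 9 spots of 3 types -> 0 (below the 10-spot rule)
  r <- gt_diversity_ranking(mk_classified(rep(c("a", "b", "c"), 3)), grid, cfg)
  expect_equal(r$score, 0)
  # 10 + 10 spots of two types -> 1 bit * ln(21)
  r <- gt_diversity_ranking(mk_classified(rep(c("a", "b"), 10)), grid, cfg)
  expect_equal(r$score, log(21), tolerance = 1e-12)
  expect_equal(r$score, 3.0445, tolerance = 1e-4)
  # Unclassified spots are excluded from proportions and N by default
  r <- gt_diversity_ranking(mk_classified(c(rep(c("a", "b"), 10),
                                            rep("Unclassified", 30))), grid, cfg)
  expect_equal(r$score, log(21), tolerance = 1e-12)
})

test_that("tumor ground truth counts and ranks tumor spots per window", {
  grid <- build_grid(10 * 224, 8 * 224)  # 3 windows (anchors (0..2, 0))
  cl <- data.frame(
    spot_id = 1:17,
    patch_row = c(rep(0L, 5), rep(8L, 3), rep(9L, 9)),
    patch_col = 0L,
    type = "tumor")
  rk <- gt_tumor_ranking(cl, grid, score_config())
  # window 0 holds rows 0-7 (5 tumor), window 1 rows 1-8 (3), window 2 rows 2-9 (12)
  expect_identical(rk$score, c(12, 5, 3))
  # doubling every tumor spot doubles each window's score
  cl2 <- rbind(cl, cl)
  cl2$spot_id <- seq_len(nrow(cl2))
  rk2 <- gt_tumor_ranking(cl2, grid, score_config())
  expect_identical(rk2$score, 2 * rk$score)
  expect_error(gt_tumor_ranking(data.frame(spot_id = 1, patch_row = 0L,
                                           patch_col = 0L, type = "immune"),
                                grid, score_config()), "tumor")
})

test_that("marker classification recovers planted spot types at effect >= 3x", {
  hits <- numeric(5)
  for (s in 1:5) {
    scn <- scenario_preset("margin", n = 12, seed = 300 + s,
                           marker_effect = 3)
    slide <- make_slide(scn)
    cls <- classify_spots(normalize_counts(slide$counts),
                          scn$markers)
    keep <- !is.na(slide$spot_truth) & cls$type != "Unclassified"
    hits[s] <- mean(cls$type[keep] == slide$spot_truth[keep])
  }
  expect_gt(mean(hits), 0.9)
})
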